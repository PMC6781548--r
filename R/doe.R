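# Design-of-experiments style evaluation of a study table: main-effects
# multiple linear regression with scaled-and-centered coefficients, and a
# response correlation matrix. Continuous factors are centered to the
# middle of their design span and scaled to +/-1 at its edges; the
# categorical composition factor is deviation-coded so that its level
# coefficients sum to zero and are directly comparable on bar plots.
# Coefficient magnitudes from other scaling conventions will differ; sign
# and ordering are the meaningful output.

#' Factor/response table of a stability study
#'
#' One row per condition and sampling time, with the design factors
#' (`time_days`, `temp_C`, `aw`, and `composition` — the PEG:SAXA ratio as
#' a categorical factor) and one numeric column per requested response
#' taken from the observations (censored values enter as the stored LOQ).
#'
#' @param datasets List of [stability_dataset()], e.g. from
#'   [generate_study()].
#' @param responses Response species to extract (default SCA, ESCA, SFA,
#'   F, FA, pH).
#' @param drop_time_zero Drop the time-0 rows (all responses at or below
#'   the LOQ)? Default `TRUE`, matching evaluation windows that start at
#'   the first pull.
#' @return Data frame of class `factor_table`.
#' @export
study_factor_table <- function(datasets,
                               responses = c("SCA", "ESCA", "SFA",
                                             "F", "FA", "pH"),
                               drop_time_zero = TRUE) {
  rows <- lapply(datasets, function(d) {
    o <- d$observations
    times <- sort(unique(o$time_days))
    resp <- sapply(responses, function(s) {
      v <- o$value[o$species == s][match(times, o$time_days[o$species == s])]
      if (all(is.na(v))) stop("response ", s, " missing from condition ",
                              d$condition_id, call. = FALSE)
      v
    })
    data.frame(time_days = times, temp_C = d$env$temp_C, aw = d$env$aw,
               composition = d$env$peg_saxa_ratio, resp,
               check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (drop_time_zero) tab <- tab[tab$time_days > 0, , drop = FALSE]
  tab$composition <- factor(tab$composition)
  class(tab) <- c("factor_table", "data.frame")
  tab
}

# Center to the design-span midpoint, scale to half the span.
scale_to_design_span <- function(x) {
  mid <- (max(x) + min(x)) / 2
  half <- (max(x) - min(x)) / 2
  if (half == 0) return(NULL)
  (x - mid) / half
}

#' Scaled-and-centered main-effects regression of one response
#'
#' Ordinary least squares of the (optionally log-transformed) response on
#' the main effects only: continuous factors centered and scaled to their
#' design span (+/-1 at the edges), the composition factor deviation-coded
#' with one reported coefficient per level (summing to zero). Alongside
#' R-squared, Q-squared is reported as `1 - PRESS / SS_tot` with PRESS from
#' exact leave-one-out cross-validation.
#'
#' @param table A [study_factor_table()].
#' @param response Name of the response column.
#' @param log_transform Regress `log(response)`? (Requires strictly
#'   positive values.) Default `FALSE`.
#' @return List with `coefficients` (named: intercept, continuous factors,
#'   `composition_<level>` per level), `R2`, `Q2`, `n`, `response`.
#' @export
mlr_scaled_centered <- function(table, response, log_transform = FALSE) {
  if (!response %in% names(table)) {
    stop("unknown response: ", response, call. = FALSE)
  }
  y <- table[[response]]
  if (log_transform) {
    if (any(y <= 0)) {
      stop("log transform requires strictly positive response values",
           call. = FALSE)
    }
    y <- log(y)
  }
  cont <- c("time_days", "temp_C", "aw")
  cols <- list(intercept = rep(1, nrow(table)))
  for (f in cont) {
    s <- scale_to_design_span(table[[f]])
    if (!is.null(s)) cols[[f]] <- s
  }
  lev <- levels(table$composition)
  L <- length(lev)
  if (L > 1) {
    for (l in seq_len(L - 1)) {
      v <- ifelse(table$composition == lev[l], 1,
                  ifelse(table$composition == lev[L], -1, 0))
      cols[[paste0("composition_", lev[l])]] <- v
    }
  }
  X <- do.call(cbind, cols)
  n <- nrow(X)
  if (n < ncol(X) + 2) {
    stop("need at least n_params + 2 rows", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("constant response; coefficients set to 0 and R2 reported as 0",
            call. = FALSE)
    cf <- setNames(rep(0, ncol(X) + (L > 1)), c(colnames(X),
      if (L > 1) paste0("composition_", lev[L])))
    cf["intercept"] <- y[1]
    return(list(coefficients = cf, R2 = 0, Q2 = 0, n = n,
                response = response))
  }
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  resid <- fit$residuals
  h <- rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2)
  press <- sum((resid / (1 - h))^2)
  cf <- beta
  if (L > 1) {
    gam <- beta[paste0("composition_", lev[-L])]
    cf[paste0("composition_", lev[L])] <- -sum(gam)
  }
  list(coefficients = cf,
       R2 = 1 - sum(resid^2) / sst,
       Q2 = 1 - press / sst,
       n = n, response = response)
}

#' Pearson correlation matrix between responses
#'
#' @param table A [study_factor_table()].
#' @param responses Response column names (at least two; table must have at
#'   least 3 rows).
#' @return Symmetric matrix of Pearson r with unit diagonal. Rows/columns
#'   of zero-variance responses are reported as `NA` (undefined), not 0.
#' @export
correlation_matrix <- function(table, responses) {
  missing <- setdiff(responses, names(table))
  if (length(missing)) {
    stop("unknown responses: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(table[responses])
  if (nrow(m) < 3) stop("need at least 3 rows", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  r
}
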