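#' Metabolomics statistics
#'
#' The abundance table convention throughout this file: a wide data frame
#' whose first column `sample` holds sample ids and whose remaining columns
#' hold one metabolite each (non-negative peak areas, or log2 values after
#' [log2_transform()]). The companion design table has columns `sample`,
#' `group`, `batch`, `is_qc`.
#'
#' @name metabolomics-stats
NULL

abundance_values <- function(abundance) {
  if (!"sample" %in% names(abundance)) {
    abort("abundance table needs a 'sample' column",
          class = "metafoot_format_error")
  }
  m <- as.matrix(abundance[, setdiff(names(abundance), "sample"), drop = FALSE])
  rownames(m) <- abundance$sample
  storage.mode(m) <- "double"
  m
}

rebuild_abundance <- function(m, abundance) {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(sample = abundance$sample), out)
  out
}

check_design <- function(abundance, design) {
  need <- c("sample", "group", "batch", "is_qc")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols) > 0) {
    abort(sprintf("design table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "metafoot_format_error")
  }
  missing_samples <- setdiff(abundance$sample, design$sample)
  if (length(missing_samples) > 0) {
    abort(sprintf("sample(s) absent from design: %s",
                  paste(missing_samples, collapse = ", ")),
          class = "metafoot_format_error")
  }
  design[match(abundance$sample, design$sample), ]
}

#' Drop metabolites that are unstable across QC samples
#'
#' Pooled QC samples are injected repeatedly through an LC-MS run; a
#' metabolite whose relative standard deviation (sd/mean) across them
#' reaches the threshold is considered unreliably measured and removed.
#'
#' @param abundance Wide abundance table (see [metabolomics-stats]).
#' @param design Design table; rows with `is_qc = TRUE` define the QC set
#'   (at least 2 required).
#' @param threshold RSD cutoff as a fraction; default 0.30 (metabolites
#'   with RSD >= 30% are dropped).
#' @return The abundance table without the failing metabolites; the drops
#'   (metabolite, rsd) are attached as attribute `"qc_dropped"`.
#' @export
qc_rsd_filter <- function(abundance, design, threshold = 0.30) {
  design <- check_design(abundance, design)
  m <- abundance_values(abundance)
  qc <- m[design$is_qc, , drop = FALSE]
  if (nrow(qc) < 2) {
    abort("QC RSD filtering needs at least 2 QC samples",
          class = "metafoot_config_error")
  }
  mu <- colMeans(qc)
  rsd <- apply(qc, 2, sd) / mu
  rsd[!is.finite(rsd)] <- Inf  # zero-mean QC signal: unmeasurable, drop
  drop <- rsd >= threshold
  dropped <- tibble(metabolite = colnames(qc)[drop], rsd = unname(rsd[drop]))
  if (nrow(dropped) > 0) {
    inform(sprintf("qc_rsd_filter: dropping %d metabolite(s) with QC RSD >= %g",
                   nrow(dropped), threshold))
  }
  out <- abundance[, c("sample", colnames(qc)[!drop]), drop = FALSE]
  attr(out, "qc_dropped") <- dropped
  out
}

#' Normalize peak areas to each sample's total ion count
#'
#' Divides every area by the sample's total over the reported metabolites,
#' correcting sample-handling and injection-volume variation; each
#' normalized row sums to 1.
#'
#' @param abundance Wide abundance table of raw areas.
#' @return The normalized abundance table.
#' @export
tic_normalize <- function(abundance) {
  m <- abundance_values(abundance)
  if (any(m < 0, na.rm = TRUE)) {
    abort("peak areas must be non-negative", class = "metafoot_domain_error")
  }
  totals <- rowSums(m)
  bad <- which(!is.finite(totals) | totals <= 0)
  if (length(bad) > 0) {
    abort(sprintf("cannot TIC-normalize sample(s) with zero total ion count: %s",
                  paste(rownames(m)[bad], collapse = ", ")),
          class = "metafoot_normalization_error")
  }
  rebuild_abundance(m / totals, abundance)
}

#' Log2-transform abundances with a half-minimum pseudo-count
#'
#' Adds half of the smallest positive value in the table before taking
#' log2, so zero areas stay finite while large areas are essentially
#' unchanged. Linear modelling and moderated t-statistics assume roughly
#' homoskedastic log-scale data, so this precedes batch regression and
#' differential analysis.
#'
#' @param abundance Wide abundance table (areas or TIC-normalized areas).
#' @param pseudo Optional explicit pseudo-count; default half the minimum
#'   positive value.
#' @return The log2 abundance table.
#' @export
log2_transform <- function(abundance, pseudo = NULL) {
  m <- abundance_values(abundance)
  if (is.null(pseudo)) {
    pos <- m[m > 0]
    if (length(pos) == 0) {
      abort("no positive values to anchor the pseudo-count",
            class = "metafoot_domain_error")
    }
    pseudo <- min(pos) / 2
  }
  rebuild_abundance(log2(m + pseudo), abundance)
}

#' Regress out additive batch effects
#'
#' Fits, per metabolite, least squares on group + batch indicator
#' covariates and subtracts the fitted batch terms while retaining the
#' group terms — the standard linear-model batch correction for designs
#' where batch is not confounded with the biological contrast. Expects
#' log-scale data; QC samples are excluded (and dropped from the output)
#' since they carry no group label.
#'
#' @param abundance Wide log2 abundance table.
#' @param design Design table.
#' @return The batch-corrected abundance table (non-QC samples only).
#' @export
remove_batch_effect <- function(abundance, design) {
  design <- check_design(abundance, design)
  keep <- !design$is_qc
  abundance <- abundance[keep, , drop = FALSE]
  design <- design[keep, , drop = FALSE]
  if (any(is.na(design$group) | design$group == "") ||
      any(is.na(design$batch) | design$batch == "")) {
    abort("non-QC samples need non-empty group and batch labels",
          class = "metafoot_format_error")
  }
  batches <- unique(design$batch)
  if (length(batches) < 2) {
    warn("single batch: remove_batch_effect is the identity")
    return(abundance)
  }
  group <- factor(design$group)
  batch <- factor(design$batch)
  x_group <- model.matrix(~group)
  x_batch <- model.matrix(~batch)[, -1, drop = FALSE]
  x <- cbind(x_group, x_batch)
  if (qr(x)$rank < ncol(x)) {
    abort("batch is confounded with the group design; cannot separate effects",
          class = "metafoot_design_error")
  }
  m <- abundance_values(abundance)
  beta <- qr.coef(qr(x), m)
  beta_batch <- beta[seq.int(ncol(x_group) + 1, ncol(x)), , drop = FALSE]
  corrected <- m - x_batch %*% beta_batch
  rebuild_abundance(corrected, abundance)
}

# Moments fit of the scaled-inverse-chi-square prior on residual variances:
# log s^2 is a shifted log-F; matching mean and variance of
# e = log s^2 - digamma(d/2) + log(d/2) gives the prior df d0 (via trigamma
# inversion) and prior variance s0^2 in closed form.
fit_variance_prior <- function(s2, df) {
  n <- length(s2)
  if (n < 3) {
    warn("fewer than 3 metabolites: no variance shrinkage (d0 = 0)")
    return(list(d0 = 0, s0_sq = NA_real_))
  }
  s2 <- pmax(s2, 1e-300)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- var(e) - trigamma(df / 2)
  if (!is.finite(e_var)) {
    warn("variance prior fit failed; falling back to ordinary t (d0 = 0)")
    return(list(d0 = 0, s0_sq = NA_real_))
  }
  if (e_var <= 0) {
    # observed spread no wider than sampling noise: infinitely strong prior,
    # anchored at the pooled mean variance (unbiased for the common sigma^2,
    # and exact when every metabolite shows the same residual variance)
    return(list(d0 = Inf, s0_sq = mean(s2)))
  }
  d0 <- 2 * trigamma_inverse(e_var)
  list(d0 = d0, s0_sq = exp(e_mean + digamma(d0 / 2) - log(d0 / 2)))
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (convex, monotone)
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Fit empirical-Bayes moderated two-group t-statistics
#'
#' Per metabolite, the pooled two-sample residual variance s_g^2 (d_g
#' residual df) is shrunk toward a prior variance s0^2 fitted across
#' metabolites by moments on log s_g^2: the posterior variance is
#' s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g) and the moderated
#' statistic t = (mean1 - mean2) / (s_tilde sqrt(1/n1 + 1/n2)) is referred
#' to a t distribution on d0 + d_g df. With d0 = 0 this is the ordinary
#' pooled t; as d0 grows every variance collapses to s0^2.
#'
#' @param abundance Wide log2 abundance table (batch-corrected if needed).
#' @param design Design table; QC rows are ignored.
#' @param contrast Character pair `c(group1, group2)`; positive t means
#'   higher in `group1`.
#' @param d0 Optional prior df override (0 forces the ordinary t; default
#'   `NULL` fits it from the data).
#' @return A `moderated_fit` object; [tidy()] extracts the per-metabolite
#'   table (`metabolite`, `log2fc`, `t_value`, `p`, `adj_p`, `contrast`),
#'   [glance()] the fitted hyperparameters.
#' @export
fit_moderated_t <- function(abundance, design, contrast, d0 = NULL) {
  if (length(contrast) != 2) {
    abort("contrast must name exactly two groups", class = "metafoot_contrast_error")
  }
  design <- check_design(abundance, design)
  keep <- !design$is_qc
  abundance <- abundance[keep, , drop = FALSE]
  design <- design[keep, , drop = FALSE]
  absent <- setdiff(contrast, design$group)
  if (length(absent) > 0) {
    abort(sprintf("contrast group(s) absent from design: %s",
                  paste(absent, collapse = ", ")),
          class = "metafoot_contrast_error")
  }
  m <- abundance_values(abundance)
  i1 <- design$group == contrast[1]
  i2 <- design$group == contrast[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) {
    abort("each contrast group needs at least 2 samples",
          class = "metafoot_contrast_error")
  }
  # column order must not matter: compute on sorted columns, report sorted
  m <- m[, radix_order(colnames(m)), drop = FALSE]
  mean1 <- colMeans(m[i1, , drop = FALSE])
  mean2 <- colMeans(m[i2, , drop = FALSE])
  var1 <- apply(m[i1, , drop = FALSE], 2, var)
  var2 <- apply(m[i2, , drop = FALSE], 2, var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * var1 + (n2 - 1) * var2) / df
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, df)
  } else {
    prior <- list(d0 = d0,
                  s0_sq = if (d0 > 0) mean(s2) else NA_real_)
  }
  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s0_sq, length(s2))
  } else if (prior$d0 == 0) {
    s2
  } else {
    (prior$d0 * prior$s0_sq + df * s2) / (prior$d0 + df)
  }
  log2fc <- mean1 - mean2
  t_val <- log2fc / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- min(prior$d0 + df, .Machine$double.xmax)
  p <- 2 * pt(-abs(t_val), df = df_total)
  table <- tibble(
    metabolite = colnames(m),
    log2fc = unname(log2fc),
    t_value = unname(t_val),
    p = unname(p),
    adj_p = bh_adjust(unname(p)),
    contrast = paste(contrast, collapse = "-")
  )
  structure(
    list(table = table, d0 = prior$d0, s0_sq = prior$s0_sq,
         df_residual = df, n1 = n1, n2 = n2,
         contrast = paste(contrast, collapse = "-")),
    class = "moderated_fit"
  )
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> %s: %d metabolites, d0 = %.3g, s0^2 = %.3g, residual df = %d\n",
              x$contrast, nrow(x$table), x$d0, x$s0_sq, x$df_residual))
  invisible(x)
}

#' @rdname fit_moderated_t
#' @param x A `moderated_fit` object.
#' @param ... Unused.
#' @export
tidy.moderated_fit <- function(x, ...) x$table

#' @rdname fit_moderated_t
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(d0 = x$d0, s0_sq = x$s0_sq, df_residual = x$df_residual,
         n_metabolites = nrow(x$table), n1 = x$n1, n2 = x$n2,
         contrast = x$contrast)
}

#' Moderated differential table in one call
#'
#' Convenience wrapper: [fit_moderated_t()] then [tidy()].
#'
#' @inheritParams fit_moderated_t
#' @return The per-metabolite differential tibble.
#' @export
moderated_t <- function(abundance, design, contrast, d0 = NULL) {
  tidy(fit_moderated_t(abundance, design, contrast, d0 = d0))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in the input order;
#' adjusted values never fall below the raw ones.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]", class = "metafoot_domain_error")
  }
  p.adjust(p, method = "BH")
}
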