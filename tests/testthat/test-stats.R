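test_that("QC RSD filtering drops unstable metabolites", {
  ab <- tibble::tibble(
    sample = c("s1", "s2", "q1", "q2", "q3"),
    stable = c(1, 2, 100, 100, 100),
    wobbly = c(1, 2, 10, 20, 30)  # RSD = 10/20 = 0.5
  )
  design <- tibble::tibble(
    sample = ab$sample,
    group = c("CASE", "CTRL", "QC", "QC", "QC"),
    batch = "B1",
    is_qc = c(FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  out <- suppressMessages(qc_rsd_filter(ab, design))
  expect_setequal(setdiff(names(out), "sample"), "stable")
  expect_equal(attr(out, "qc_dropped")$metabolite, "wobbly")
  expect_equal(attr(out, "qc_dropped")$rsd, 0.5)

  lax <- qc_rsd_filter(ab, design, threshold = 1.0)
  expect_setequal(setdiff(names(lax), "sample"), c("stable", "wobbly"))

  one_qc <- design |> dplyr::mutate(is_qc = sample == "q2")
  expect_error(qc_rsd_filter(ab, one_qc), class = "metafoot_config_error")
})

test_that("TIC normalization makes every sample sum to one", {
  ab <- tibble::tibble(sample = "s1", A = 2, B = 3, C = 5)
  out <- tic_normalize(ab)
  expect_equal(unlist(out[1, c("A", "B", "C")]), c(A = 0.2, B = 0.3, C = 0.5))
  expect_equal(tic_normalize(tibble::tibble(sample = "s1", A = 7))$A, 1)

  set.seed(3)
  wide <- tibble::as_tibble(matrix(rexp(200, 1e-5), nrow = 10,
                                   dimnames = list(NULL, paste0("m", 1:20))))
  wide <- dplyr::bind_cols(tibble::tibble(sample = paste0("s", 1:10)), wide)
  normed <- tic_normalize(wide)
  expect_equal(rowSums(normed[, -1]), rep(1, 10))
  # identical samples normalize identically
  two <- wide[c(1, 1), ]; two$sample <- c("a", "b")
  normed2 <- tic_normalize(two)
  expect_equal(unlist(normed2[1, -1]), unlist(normed2[2, -1]))

  expect_error(tic_normalize(tibble::tibble(sample = c("ok", "empty"),
                                            A = c(1, 0), B = c(2, 0))),
               "empty", class = "metafoot_normalization_error")
})

make_batch_data <- function(seed, n_per_cell = 3, n_mets = 40, beta = NULL,
                            noise = 0.1) {
  set.seed(seed)
  design <- expand.grid(group = c("CASE", "CTRL"), batch = c("B1", "B2"),
                        rep = seq_len(n_per_cell),
                        stringsAsFactors = FALSE)
  design <- tibble::tibble(
    sample = sprintf("s%02d", seq_len(nrow(design))),
    group = design$group, batch = design$batch, is_qc = FALSE
  )
  base <- rnorm(n_mets, 12, 1)
  if (is.null(beta)) beta <- rnorm(n_mets, 0, 1)
  m <- t(vapply(seq_len(nrow(design)), function(i) {
    base + (design$batch[i] == "B2") * beta + rnorm(n_mets, 0, noise)
  }, numeric(n_mets)))
  colnames(m) <- sprintf("m%02d", seq_len(n_mets))
  list(abundance = dplyr::bind_cols(tibble::tibble(sample = design$sample),
                                    tibble::as_tibble(m)),
       design = design, beta = beta)
}

test_that("batch regression removes additive batch structure", {
  # constant +delta on batch 2, balanced groups: corrected batch means equal
  d <- make_batch_data(1, beta = rep(2.5, 40), noise = 0)
  corrected <- remove_batch_effect(d$abundance, d$design)
  m <- as.matrix(corrected[, -1])
  b <- d$design$batch
  expect_equal(colMeans(m[b == "B1", ]), colMeans(m[b == "B2", ]),
               tolerance = 1e-10)

  # per-metabolite batch coefficients are recovered within Monte-Carlo error
  d2 <- make_batch_data(2)
  corrected2 <- remove_batch_effect(d2$abundance, d2$design)
  recovered <- colMeans(as.matrix(d2$abundance[d2$design$batch == "B2", -1])) -
    colMeans(as.matrix(corrected2[d2$design$batch == "B2", -1]))
  expect_equal(unname(recovered), d2$beta, tolerance = 0.25)
  expect_lt(mean(abs(recovered - d2$beta)), 3 * 0.1 * sqrt(2 / 6))
})

test_that("degenerate batch designs are caught", {
  d <- make_batch_data(3)
  single <- d$design |> dplyr::mutate(batch = "B1")
  expect_warning(out <- remove_batch_effect(d$abundance, single), "identity")
  expect_equal(out, d$abundance)

  confounded <- d$design |>
    dplyr::mutate(batch = ifelse(group == "CASE", "B1", "B2"))
  expect_error(remove_batch_effect(d$abundance, confounded),
               class = "metafoot_design_error")
})

test_that("with d0 = 0 the moderated statistic is the classical pooled t", {
  d <- make_null_data(1)
  fit <- fit_moderated_t(d$abundance, d$design, c("CASE", "CTRL"), d0 = 0)
  expect_equal(setNames(tidy(fit)$t_value, tidy(fit)$metabolite),
               pooled_t_oracle(d$abundance, d$design, c("CASE", "CTRL")))
  expect_equal(glance(fit)$d0, 0)
})

test_that("identical residual variances shrink onto themselves", {
  # every metabolite shows the exact same within-group pattern (0, 1, 2),
  # so all pooled variances equal var(c(0, 1, 2)); only the means differ
  set.seed(4)
  n_mets <- 20
  m <- vapply(seq_len(n_mets), function(j) {
    c(c(0, 1, 2) + rnorm(1, 10, 2), c(0, 1, 2) + rnorm(1, 10, 2))
  }, numeric(6))
  colnames(m) <- sprintf("m%02d", seq_len(n_mets))
  ab <- dplyr::bind_cols(tibble::tibble(sample = sprintf("s%d", 1:6)),
                         tibble::as_tibble(m))
  design <- tibble::tibble(sample = ab$sample,
                           group = rep(c("CTRL", "CASE"), each = 3),
                           batch = "B1", is_qc = FALSE)
  fit <- fit_moderated_t(ab, design, c("CASE", "CTRL"))
  expect_true(is.infinite(glance(fit)$d0))
  expect_equal(glance(fit)$s0_sq, var(c(0, 1, 2)), tolerance = 1e-12)
})

test_that("moderated t agrees with the limma empirical-Bayes cross-check", {
  skip_if_not_installed("limma")
  d <- make_null_data(7, n_mets = 80, n_per_group = 5)
  fit <- fit_moderated_t(d$abundance, d$design, c("CASE", "CTRL"))
  m <- t(as.matrix(d$abundance[, -1]))
  colnames(m) <- d$abundance$sample
  design_mat <- model.matrix(~ 0 + factor(d$design$group,
                                          levels = c("CASE", "CTRL")))
  colnames(design_mat) <- c("CASE", "CTRL")
  lfit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(m, design_mat),
    limma::makeContrasts(CASE - CTRL, levels = design_mat)
  ))
  tab <- tidy(fit)
  expect_equal(tab$t_value, unname(lfit$t[tab$metabolite, 1]),
               tolerance = 1e-8)
  expect_equal(tab$p, unname(lfit$p.value[tab$metabolite, 1]),
               tolerance = 1e-8)
  expect_equal(glance(fit)$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(glance(fit)$s0_sq, lfit$s2.prior, tolerance = 1e-6)
})

test_that("moderated t is invariant to metabolite and sample order", {
  d <- make_null_data(11)
  base <- moderated_t(d$abundance, d$design, c("CASE", "CTRL"))
  set.seed(1)
  ab_perm <- d$abundance[sample(nrow(d$abundance)),
                         c(1, 1 + sample(ncol(d$abundance) - 1))]
  expect_equal(moderated_t(ab_perm, d$design, c("CASE", "CTRL")), base)
})

test_that("a planted effect lifts |t| above the null background", {
  set.seed(21)
  n_mets <- 200; n <- 5
  planted <- seq_len(20)  # 10% of metabolites at +2 sd
  m <- matrix(rnorm(n_mets * 2 * n, 10, 1), nrow = 2 * n)
  m[seq_len(n), planted] <- m[seq_len(n), planted] + 2
  colnames(m) <- sprintf("m%03d", seq_len(n_mets))
  ab <- dplyr::bind_cols(tibble::tibble(sample = sprintf("s%02d", 1:(2 * n))),
                         tibble::as_tibble(m))
  design <- tibble::tibble(sample = ab$sample,
                           group = rep(c("CASE", "CTRL"), each = n),
                           batch = "B1", is_qc = FALSE)
  tab <- moderated_t(ab, design, c("CASE", "CTRL"))
  is_planted <- tab$metabolite %in% sprintf("m%03d", planted)
  expect_gt(mean(abs(tab$t_value[is_planted])),
            mean(abs(tab$t_value[!is_planted])))
})

test_that("contrast validation catches bad requests", {
  d <- make_null_data(5)
  expect_error(fit_moderated_t(d$abundance, d$design, c("CASE", "GONE")),
               "GONE", class = "metafoot_contrast_error")
  expect_error(fit_moderated_t(d$abundance, d$design, "CASE"),
               class = "metafoot_contrast_error")
})

test_that("BH adjustment matches the hand step-up and is order-stable", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "metafoot_domain_error")

  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p - 1e-15))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm])[order(perm)], adj)
  }
})
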