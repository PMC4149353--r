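two_group_matrix <- function(n_genes, n_per_group, seed, sd = 1,
                             delta = NULL) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * 2 * n_per_group, mean = 8, sd = sd),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(2 * n_per_group))))
  if (!is.null(delta))
    vals[, n_per_group + seq_len(n_per_group)] <-
      vals[, n_per_group + seq_len(n_per_group)] + delta
  groups <- setNames(rep(c("control", "disease"), each = n_per_group),
                     colnames(vals))
  expression_matrix(vals, groups)
}

test_that("with prior df forced to 0 the moderated t is the classical pooled t", {
  for (seed in c(1, 2, 3)) {
    em <- two_group_matrix(50, 5, seed)
    res <- moderated_t(em, prior_df = 0)
    x1 <- em$values[, em$groups == "control"]
    x2 <- em$values[, em$groups == "disease"]
    expect_equal(res$t, unname(pooled_t_oracle(x1, x2)), tolerance = 1e-10)
  }
})

test_that("with infinite prior df every gene is scored at the common variance", {
  em <- two_group_matrix(80, 4, 9)
  res <- moderated_t(em, prior_df = Inf)
  s02 <- attr(res, "prior_var")
  n <- 4
  expect_equal(res$t, res$log2fc / sqrt(s02 * (2 / n)), tolerance = 1e-12)
})

test_that("the fitted prior agrees with limma's empirical Bayes machinery", {
  set.seed(4)
  n_genes <- 200; npg <- 5
  sds <- sqrt(5 / stats::rchisq(n_genes, df = 5))  # heterogeneous variances
  vals <- matrix(rnorm(n_genes * 2 * npg, mean = 8, sd = rep(sds, 2 * npg)),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(2 * npg))))
  em <- expression_matrix(vals, setNames(rep(c("control", "disease"),
                                             each = npg), colnames(vals)))
  res <- moderated_t(em)
  expect_true(is.finite(attr(res, "prior_df")))
  design <- cbind(1, em$groups == "disease")
  fit <- limma::eBayes(limma::lmFit(em$values, design))
  expect_equal(attr(res, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("under the null the moderated test keeps its size", {
  em <- two_group_matrix(2000, 10, 27, sd = 0.5)
  res <- moderated_t(em)
  expect_true(abs(mean(res$p < 0.05) - 0.05) <= 0.02)
  expect_lt(mean(abs(res$t) > 10), 0.001)
})

test_that("degenerate zero-variance genes are handled as documented", {
  vals <- matrix(c(rep(1, 8),               # flat, no difference
                   rep(c(1, 2), each = 4),  # flat per group, clear difference
                   rnorm(8)), nrow = 3, byrow = TRUE,
                 dimnames = list(c("flat", "step", "noisy"), paste0("s", 1:8)))
  em <- expression_matrix(vals, setNames(rep(c("a", "b"), each = 4),
                                         paste0("s", 1:8)))
  expect_message(res <- moderated_t(em, prior_df = 0), "variance floor")
  expect_equal(res$t[res$gene == "flat"], 0)
  expect_equal(res$p[res$gene == "flat"], 1)
  expect_lt(res$p[res$gene == "step"], 1e-10)
})

test_that("DEG calling applies the strict linear fold-change rule", {
  rec <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(log2(1.25), log2(1.20), log2(0.5), 0.05),
                    t = 0, p = c(0.5, 0.5, 0.01, 0.9),
                    stringsAsFactors = FALSE)
  dl <- call_degs(rec)                       # fold-change-only rule
  expect_true("a" %in% dl$up)                # 1.25 > 1.2
  expect_false("b" %in% c(dl$up, dl$down))   # 1.20 is not above 1.2
  expect_true("c" %in% dl$down)              # |FC| = 2 downward
  dl2 <- call_degs(rec, p_cut = 0.05)        # protein-list rule
  expect_identical(deg_genes(dl2), "c")
  expect_error(call_degs(rec, fc_cut = 0.8), "fc_cut")
})

test_that("raising the fold-change cutoff never adds a gene", {
  set.seed(42)
  rec <- data.frame(gene = sprintf("g%03d", 1:300),
                    log2fc = rnorm(300, sd = 0.6), t = 0,
                    p = runif(300), stringsAsFactors = FALSE)
  cuts <- c(1, 1.1, 1.2, 1.5, 2, 3)
  called <- lapply(cuts, function(fc) deg_genes(call_degs(rec, fc_cut = fc)))
  for (i in seq_along(cuts)[-1])
    expect_true(all(called[[i]] %in% called[[i - 1]]))
})

test_that("overlap percentages reproduce the printed concordance arithmetic", {
  a <- sprintf("x%04d", 1:1157)
  b <- c(a[1:394], sprintf("y%04d", 1:1000))
  ov <- overlap_stats(a, b, reference = "a")
  expect_equal(ov$n_intersection, 394)
  expect_equal(ov$percent_of_reference, 34.1)

  a2 <- sprintf("x%04d", 1:1305)
  b2 <- c(a2[1:109], sprintf("y%04d", 1:600))
  ov2 <- overlap_stats(a2, b2, reference = "a")
  expect_equal(ov2$n_intersection, 109)
  expect_equal(ov2$percent_of_reference, 8.4)

  expect_equal(overlap_stats(c("a", "b"), c("c"), "a")$percent_of_reference, 0)
  expect_error(overlap_stats(character(), c("a"), "a"), "empty")
})

test_that("overlap counts match brute-force intersection and are symmetric", {
  set.seed(7)
  for (i in 1:20) {
    a <- sample(sprintf("g%02d", 1:40), sample(5:30, 1))
    b <- sample(sprintf("g%02d", 1:40), sample(5:30, 1))
    ni <- sum(!is.na(match(unique(a), unique(b))))
    expect_equal(overlap_stats(a, b, "a")$n_intersection, ni)
    expect_equal(overlap_stats(b, a, "b")$n_intersection, ni)
  }
})
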