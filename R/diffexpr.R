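#' Empirical-Bayes moderated t-test for two-group expression data
#'
#' Per-gene two-sample comparison with variance moderation. For gene g with
#' pooled residual variance `s2_g` on `d_g = n1 + n2 - 2` degrees of
#' freedom, a scaled inverse-chi-square prior `(d0, s0^2)` is estimated by
#' method of moments on `log s2_g` (mean/variance matching through the
#' digamma/trigamma identities, trigamma inversion by Newton's method). The
#' posterior variance
#' `s2_tilde = (d0 * s0^2 + d_g * s2_g) / (d0 + d_g)` replaces `s2_g` in the
#' classical pooled statistic, and two-sided p-values come from a t
#' distribution on `d0 + d_g` degrees of freedom.
#'
#' `log2fc` is the difference of group means (second group label minus
#' first, in the order of `sort(unique(groups))` unless `reference` names
#' the baseline group); data are assumed to be on the log2 scale, so this
#' difference is the log2 fold change.
#'
#' Degenerate genes: zero pooled variance with zero mean difference gives
#' `t = 0, p = 1`; zero pooled variance with a nonzero difference is scored
#' at a machine-minimum variance floor (a message reports how many genes
#' were floored). Such genes are excluded from the prior fit.
#'
#' @param em an [expression_matrix] with exactly two groups, each of size
#'   >= 2.
#' @param reference optional group label to use as baseline (denominator of
#'   the fold change).
#' @param prior_df override for the prior degrees of freedom `d0`: `NULL`
#'   (estimate, default), `0` (no moderation; classical pooled t) or `Inf`
#'   (full shrinkage to the common variance `s0^2`).
#' @return data frame with one row per gene: `gene`, `log2fc`, `t`, `p`;
#'   attributes `prior_df` and `prior_var` carry the fitted `(d0, s0^2)`.
#' @export
moderated_t <- function(em, reference = NULL, prior_df = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  labs <- sort(unique(em$groups))
  if (length(labs) != 2L)
    stop("moderated_t requires exactly two groups, got ", length(labs))
  if (!is.null(reference)) {
    if (!reference %in% labs) stop("reference group not in design")
    labs <- c(reference, setdiff(labs, reference))
  }
  x1 <- em$values[, em$groups == labs[1], drop = FALSE]
  x2 <- em$values[, em$groups == labs[2], drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  d_g <- n1 + n2 - 2
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, var); v2 <- apply(x2, 1, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d_g
  delta <- m2 - m1

  ok <- s2 > 0
  if (is.null(prior_df)) {
    fit <- fit_variance_prior(s2[ok], d_g)
    d0 <- fit$d0; s02 <- fit$s02
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) fit_variance_prior(s2[ok], d_g)$s02 else NA_real_
  }

  s2post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    if (d0 == 0) s2 else (d0 * s02 + d_g * s2) / (d0 + d_g)
  zero <- !ok & s2post <= 0
  if (any(zero & delta != 0)) {
    message(sum(zero & delta != 0),
            " gene(s) with zero variance and nonzero difference scored at the variance floor")
  }
  s2post[zero] <- .Machine$double.xmin
  tt <- delta / sqrt(s2post * (1 / n1 + 1 / n2))
  tt[zero & delta == 0] <- 0
  df_total <- d0 + d_g
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(tt)) else
    2 * pt(-abs(tt), df = df_total)
  p[zero & delta == 0] <- 1
  res <- data.frame(gene = rownames(em$values), log2fc = delta, t = tt, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "prior_df") <- d0
  attr(res, "prior_var") <- s02
  attr(res, "residual_df") <- d_g
  res
}

# moment fit of the scaled inverse-chi-square variance prior on log s2:
# E[log s2] and Var[log s2] under s2 ~ s0^2 * F(d, d0) give s0^2 and d0 via
# digamma/trigamma identities; trigamma is inverted by Newton's method.
fit_variance_prior <- function(s2, d) {
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- var(z) - trigamma(d / 2)
  if (!is.finite(ev) || ev <= 0) {
    # no excess dispersion beyond the chi-square: variances look common
    return(list(d0 = Inf, s02 = mean(s2)))
  }
  d0 <- 2 * trigamma_inverse(ev)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Call differentially expressed genes by fold change (and optional p gate)
#'
#' A gene is called when its linear fold-change magnitude `2^|log2fc|` is
#' strictly above `fc_cut`, and — when `p_cut` is supplied — its p-value is
#' at most `p_cut`. Transcript lists conventionally use the fold-change rule
#' alone (default `p_cut = NULL`); differential protein lists add
#' `p_cut = 0.05`. Direction follows the sign of `log2fc`.
#'
#' @param records data frame from [moderated_t()] (columns `gene`, `log2fc`
#'   and, if `p_cut` is used, `p`).
#' @param fc_cut linear fold-change cutoff, must be >= 1 (default 1.2).
#' @param p_cut optional p-value threshold.
#' @return An object of class `deg_list`: list with `up` and `down`
#'   (character vectors ordered by decreasing fold-change magnitude),
#'   `thresholds`, and the per-gene `records` with a `direction` column
#'   added (`up`/`down`/`null`).
#' @export
call_degs <- function(records, fc_cut = 1.2, p_cut = NULL) {
  if (fc_cut < 1) stop("fc_cut must be >= 1 (linear scale)")
  called <- 2^abs(records$log2fc) > fc_cut
  if (!is.null(p_cut)) called <- called & records$p <= p_cut
  direction <- ifelse(!called, "null", ifelse(records$log2fc > 0, "up", "down"))
  o <- order(-abs(records$log2fc), records$gene)
  up <- records$gene[o][direction[o] == "up"]
  down <- records$gene[o][direction[o] == "down"]
  records$direction <- direction
  structure(list(up = up, down = down,
                 thresholds = list(fc_cut = fc_cut, p_cut = p_cut),
                 records = records),
            class = "deg_list")
}

#' @export
print.deg_list <- function(x, ...) {
  cat("deg_list:", length(x$up), "up,", length(x$down), "down (|FC| >",
      x$thresholds$fc_cut,
      if (is.null(x$thresholds$p_cut)) "" else
        paste(", p <=", x$thresholds$p_cut), ")\n")
  invisible(x)
}

#' All called genes of a deg_list
#' @param degs a `deg_list`.
#' @param direction `"both"` (default), `"up"` or `"down"`.
#' @export
deg_genes <- function(degs, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  switch(direction, both = c(degs$up, degs$down), up = degs$up, down = degs$down)
}

#' Overlap between two gene lists
#'
#' Exact set intersection with the overlap expressed as a percentage of a
#' declared reference list (printed to one decimal, rounded half-up — the
#' convention used for cross-tissue DEG concordance figures).
#'
#' @param a,b character vectors of gene ids.
#' @param reference which list the percentage refers to: `"a"` or `"b"`.
#' @return list with `n_a`, `n_b`, `n_intersection`, `percent_of_reference`,
#'   `reference`.
#' @export
overlap_stats <- function(a, b, reference = c("a", "b")) {
  reference <- match.arg(reference)
  a <- unique(a); b <- unique(b)
  ref_n <- if (reference == "a") length(a) else length(b)
  if (ref_n == 0L) stop("reference list is empty; percentage undefined")
  ni <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_intersection = ni,
       percent_of_reference = round_half_up(100 * ni / ref_n, 1),
       reference = reference)
}
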