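#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test on per-mouse condition values. Zero
#' differences are dropped before ranking (Wilcoxon's prescription) and
#' the exact null distribution is used for n <= `exact_max` pairs: with
#' six same-sign distinct differences the minimal attainable two-sided p
#' is 2/2^6 = 0.03125.
#'
#' @param table data.frame with columns `mouse`, `condition`, and the
#'   metric named by `metric`; or `NULL` when `a`/`b` are given directly.
#' @param cond_a,cond_b the two condition labels to compare.
#' @param metric metric column name.
#' @param a,b paired numeric vectors (alternative interface).
#' @param exact_max largest n for which the exact distribution is used.
#' @return list: `p`, `statistic` (V, sum of positive-difference ranks),
#'   `n_pairs` (after dropping zeros), `n_zero_dropped`, `exact`.
#' @export
paired_wilcoxon <- function(table = NULL, cond_a = NULL, cond_b = NULL,
                            metric = "value", a = NULL, b = NULL,
                            exact_max = 25) {
  if (is.null(a)) {
    ta <- table[table$condition == cond_a, ]
    tb <- table[table$condition == cond_b, ]
    ta <- ta[order(ta$mouse), ]; tb <- tb[order(tb$mouse), ]
    if (!identical(ta$mouse, tb$mouse))
      fail("conditions '", cond_a, "' and '", cond_b,
           "' are not observed on the same mice")
    a <- ta[[metric]]; b <- tb[[metric]]
  }
  if (length(a) != length(b)) fail("paired samples differ in length")
  d <- a - b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(p = NA_real_, statistic = NA_real_, n_pairs = 0L,
                          n_zero_dropped = n_zero, exact = NA,
                          all_zero = TRUE))
  if (n < 5)
    warning("only ", n, " non-zero pairs; the exact test cannot reach ",
            "p < 0.05")
  r <- rank(abs(d))                      # midranks under ties
  v <- sum(r[d > 0])
  exact <- n <= exact_max
  if (exact) {
    # sign-flip null of W+ = sum of positive-difference ranks: convolve the
    # two equally likely contributions {0, r_i} per pair. Doubled ranks stay
    # integral under midranks.
    r2 <- as.integer(round(2 * r))
    probs <- c(1)                        # P(2*W+ = 0..)
    for (ri in r2)
      probs <- (c(probs, numeric(ri)) + c(numeric(ri), probs)) / 2
    w2 <- as.integer(round(2 * v))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = FALSE))$p.value
  }
  list(p = p, statistic = v, n_pairs = n,
       n_zero_dropped = n_zero, exact = exact, all_zero = FALSE)
}

#' Two-way repeated-measures ANOVA with Bonferroni post-hocs
#'
#' Classical within-subject decomposition (`aov` with
#' `Error(subject/(A*B))`) on a balanced design with one aggregate value
#' per subject per cell, followed by pairwise paired t-tests over the
#' levels of each factor with Bonferroni correction (raw p multiplied by
#' the number of comparisons, capped at 1).
#'
#' @param table data.frame with columns `mouse`, the two factor columns,
#'   and `value`.
#' @param factors character vector naming the two within-subject factor
#'   columns.
#' @param value value column name.
#' @return list: `anova` (data.frame: effect, df1, df2, F, p) and
#'   `posthoc` (data.frame of Bonferroni-corrected pairwise comparisons
#'   per factor).
#' @export
rm_anova_two_way <- function(table, factors, value = "value") {
  f1 <- factors[1]; f2 <- factors[2]
  d <- data.frame(mouse = factor(table$mouse),
                  A = factor(table[[f1]]), B = factor(table[[f2]]),
                  y = table[[value]])
  counts <- table(d$mouse, d$A, d$B)
  if (any(counts != 1)) {
    miss <- which(counts != 1, arr.ind = TRUE)[1, ]
    fail("design is not one value per cell: mouse ",
         dimnames(counts)[[1]][miss[1]], ", ", f1, "=",
         dimnames(counts)[[2]][miss[2]], ", ", f2, "=",
         dimnames(counts)[[3]][miss[3]])
  }
  fit <- stats::aov(y ~ A * B + Error(mouse / (A * B)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, row) {
    tab <- sm[[stratum]][[1]]
    i <- grep(row, trimws(rownames(tab)), fixed = TRUE)[1]
    Fv <- tab$`F value`[i]; pv <- tab$`Pr(>F)`[i]
    # a stratum whose sums of squares are numerically zero has no effect
    if (sum(tab$`Sum Sq`) < 1e-10 * max(1, mean(d$y)^2)) { Fv <- 0; pv <- 1 }
    data.frame(effect = row, df1 = tab$Df[i],
               df2 = tab$Df[nrow(tab)], F = Fv, p = pv)
  }
  res <- rbind(pull("Error: mouse:A", "A"),
               pull("Error: mouse:B", "B"),
               pull("Error: mouse:A:B", "A:B"))
  res$effect <- c(f1, f2, paste(f1, f2, sep = ":"))

  posthoc_factor <- function(fac) {
    levs <- levels(d[[fac]])
    prs <- utils::combn(levs, 2)
    n_cmp <- ncol(prs)
    out <- lapply(seq_len(n_cmp), function(i) {
      # average over the other factor within mouse, then paired t
      other <- setdiff(c("A", "B"), fac)
      agg <- stats::aggregate(y ~ mouse + d[[fac]], data = d, FUN = mean)
      names(agg)[2] <- "lev"
      x1 <- agg$y[agg$lev == prs[1, i]][order(agg$mouse[agg$lev == prs[1, i]])]
      x2 <- agg$y[agg$lev == prs[2, i]][order(agg$mouse[agg$lev == prs[2, i]])]
      tt <- tryCatch(stats::t.test(x1, x2, paired = TRUE),
                     error = function(e) list(statistic = NA_real_,
                                              p.value = NA_real_))
      data.frame(factor = fac, level_a = prs[1, i], level_b = prs[2, i],
                 t = unname(tt$statistic), p_raw = tt$p.value,
                 p_bonferroni = min(1, tt$p.value * n_cmp))
    })
    do.call(rbind, out)
  }
  ph <- rbind(posthoc_factor("A"), posthoc_factor("B"))
  ph$factor <- ifelse(ph$factor == "A", f1, f2)
  list(anova = res, posthoc = ph)
}

#' Apply a Bonferroni correction
#'
#' Raw p-values multiplied by the number of comparisons, capped at 1.
#'
#' @param p numeric p-values.
#' @param n_comparisons number of comparisons (default `length(p)`).
#' @return corrected p-values.
#' @export
bonferroni <- function(p, n_comparisons = length(p)) {
  pmin(1, p * n_comparisons)
}
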