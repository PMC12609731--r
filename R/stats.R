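# Nonparametric statistical battery over biomarker tables: normality /
# homoscedasticity screens, Kruskal-Wallis omnibus, pairwise Mann-Whitney
# with Cliff's delta, paired Wilcoxon signed-rank with rank-biserial r,
# chi-square for demographic contingency tables. Two-sided throughout;
# average ranks with tie-corrected variances; no multiplicity correction by
# default (exploratory convention), Holm / Benjamini-Hochberg available.

.stat_row <- function(test, statistic, p_value, effect_size = NA_real_,
                      effect_type = NA_character_, group1 = NA_character_,
                      group2 = NA_character_, n1 = NA_integer_,
                      n2 = NA_integer_, alpha_level = 0.05) {
  data.frame(test = test, statistic = statistic, p_value = p_value,
             effect_size = effect_size, effect_type = effect_type,
             group1 = group1, group2 = group2, n1 = n1, n2 = n2,
             alpha_level = alpha_level, stringsAsFactors = FALSE)
}

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov statistic against a normal with estimated mean/SD,
#' with the Lilliefors small-sample p-value approximation.
#'
#' @param x numeric sample, n >= 4, non-constant.
#' @return one-row StatResult data.frame.
#' @export
lilliefors_test <- function(x) {
  if (length(x) < 5) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("Lilliefors test undefined for a constant sample")
  r <- nortest::lillie.test(x)
  .stat_row("lilliefors", unname(r$statistic), r$p.value,
            n1 = length(x))
}

#' Levene homoscedasticity test
#'
#' Classic mean-centered Levene by default; `center = "median"` gives the
#' Brown-Forsythe variant.
#'
#' @param samples list of numeric vectors (one per group), each n >= 4.
#' @param center "mean" or "median".
#' @return one-row StatResult data.frame.
#' @export
levene_test <- function(samples, center = c("mean", "median")) {
  center <- match.arg(center)
  if (any(vapply(samples, length, 1L) < 4)) stop("need n >= 4 per sample")
  y <- unlist(samples)
  g <- factor(rep(seq_along(samples), vapply(samples, length, 1L)))
  r <- car::leveneTest(y, g, center = if (center == "mean") mean else
    stats::median)
  .stat_row(paste0("levene_", center), r[1, "F value"], r[1, "Pr(>F)"],
            n1 = length(y))
}

#' Kruskal-Wallis omnibus test
#'
#' @param samples list of >= 2 numeric vectors, each n >= 2 (the typical
#'   use case has >= 3 groups; 2 are accepted for completeness).
#' @return one-row StatResult data.frame (H with tie correction, chi-square
#'   p with k-1 df).
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2) stop("need at least 2 groups")
  if (any(vapply(samples, length, 1L) < 2)) stop("need n >= 2 per group")
  y <- unlist(samples)
  g <- factor(rep(seq_along(samples), vapply(samples, length, 1L)))
  r <- stats::kruskal.test(y, g)
  .stat_row("kruskal_wallis", unname(r$statistic), r$p.value,
            n1 = length(y))
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y)`, in `[-1, 1]`.
#' Positive delta means the first sample is stochastically larger.
#'
#' @param x,y numeric samples.
#' @return delta.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  # rank-based O((n+m) log(n+m)) formulation
  r <- rank(c(x, y))
  rx <- r[seq_along(x)]
  n_x <- length(x); n_y <- length(y)
  # sum of "wins" of x over y with ties counting 1/2
  u <- sum(rx) - n_x * (n_x + 1) / 2
  (2 * u - n_x * n_y) / (n_x * n_y)
}

#' Mann-Whitney U test (unpaired Wilcoxon) with Cliff's delta
#'
#' Two-sided; exact enumeration when both samples are untied and small,
#' normal approximation with tie correction (and continuity correction)
#' otherwise — the behavior of [stats::wilcox.test()].
#'
#' @param x,y numeric samples (n >= 1 each; p-values need n >= 3 total).
#' @return one-row StatResult data.frame with `effect_size` = Cliff's delta
#'   (positive when `x` is stochastically larger).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  r <- suppressWarnings(stats::wilcox.test(x, y))
  .stat_row("mann_whitney", unname(r$statistic), r$p.value,
            effect_size = cliffs_delta(x, y), effect_type = "cliffs_delta",
            n1 = length(x), n2 = length(y))
}

#' Rank-biserial correlation for paired samples
#'
#' `r = (W+ - W-) / (W+ + W-)` over the signed ranks of the non-zero paired
#' differences `x - y`; positive r means `x > y` dominates.
#'
#' @param x,y paired numeric samples of equal length.
#' @return r in `[-1, 1]`.
#' @export
rank_biserial <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) stop("all paired differences are zero")
  rk <- rank(abs(d))
  wp <- sum(rk[d > 0]); wm <- sum(rk[d < 0])
  (wp - wm) / (wp + wm)
}

#' Wilcoxon signed-rank test with rank-biserial correlation
#'
#' Two-sided; zero differences dropped (Wilcoxon's original treatment);
#' exact for small untied samples, normal approximation beyond — the
#' behavior of [stats::wilcox.test()] with `paired = TRUE`.
#'
#' @param x,y paired numeric samples.
#' @return one-row StatResult data.frame with `effect_size` = rank-biserial
#'   r.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (sum(x != y) < 1) stop("all paired differences are zero")
  r <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  .stat_row("wilcoxon_signed_rank", unname(r$statistic), r$p.value,
            effect_size = rank_biserial(x, y), effect_type = "rank_biserial",
            n1 = length(x), n2 = length(y))
}

#' Pearson chi-square test of independence
#'
#' No continuity correction. A warning is issued when any expected count
#' falls below 5.
#'
#' @param counts matrix of nonnegative integer counts, at least 2x2; row
#'   names are groups, column names categories.
#' @return one-row StatResult data.frame; the expected counts are attached
#'   as attribute `"expected"`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) stop("need at least a 2x2 table")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal row/column")
  r <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(r$expected < 5))
    warning("some expected counts are below 5; chi-square approximation weak")
  out <- .stat_row("chi_square", unname(r$statistic), r$p.value,
                   n1 = sum(counts))
  attr(out, "expected") <- r$expected
  out
}

#' Full group analysis of a biomarker table
#'
#' Per channel x band: Lilliefors and Levene screens, Kruskal-Wallis
#' omnibus, all pairwise Mann-Whitney tests with Cliff's delta. Per group x
#' band: paired C3-vs-C4 Wilcoxon signed-rank with rank-biserial r. Per
#' band: Kruskal-Wallis on LI plus pairwise Mann-Whitney. Optionally,
#' chi-square tests of supplied demographic contingency tables. Groups with
#' fewer than `min_n` subjects are skipped with a warning. By default no
#' multiplicity correction is applied (exploratory convention); set
#' `correction` to adjust pairwise p-values.
#'
#' @param biomarkers list with `eri` and `li` data.frames as produced by
#'   [build_biomarker_table()].
#' @param demographics optional named list of count matrices.
#' @param correction "none" (default), "holm" or "BH".
#' @param min_n minimal group size entering a comparison.
#' @return named list of StatResult data.frames: `screens`, `omnibus`,
#'   `pairwise`, `paired_c3_c4`, `li_omnibus`, `li_pairwise`,
#'   `demographics`.
#' @export
run_group_analysis <- function(biomarkers, demographics = NULL,
                               correction = c("none", "holm", "BH"),
                               min_n = 4) {
  correction <- match.arg(correction)
  eri <- biomarkers$eri
  li <- biomarkers$li
  groups <- unique(eri$group)
  screens <- list(); omnibus <- list(); pairwise <- list()
  paired <- list(); li_omni <- list(); li_pw <- list()

  grab <- function(df, value_col, ...) {
    flt <- list(...)
    sel <- rep(TRUE, nrow(df))
    for (nm in names(flt)) sel <- sel & df[[nm]] == flt[[nm]]
    df[[value_col]][sel]
  }
  usable <- function(xs) names(xs)[vapply(xs, length, 1L) >= min_n]

  for (band in unique(eri$band)) {
    for (ch in unique(eri$channel)) {
      xs <- lapply(groups, function(g)
        grab(eri, "eri_db", group = g, band = band, channel = ch))
      names(xs) <- groups
      ok <- usable(xs)
      if (length(ok) < length(groups))
        warning("groups with n < ", min_n, " skipped for ", ch, "/", band)
      xs <- xs[ok]
      tag <- function(df, g1 = NA, g2 = NA) {
        df$channel <- ch; df$band <- band
        if (!is.na(g1)) df$group1 <- g1
        if (!is.na(g2)) df$group2 <- g2
        df
      }
      for (g in ok)
        if (length(xs[[g]]) >= 5)
          screens[[length(screens) + 1]] <-
            tag(lilliefors_test(xs[[g]]), g1 = g)
      if (length(ok) >= 2)
        screens[[length(screens) + 1]] <- tag(levene_test(xs))
      if (length(ok) >= 2)
        omnibus[[length(omnibus) + 1]] <- tag(kruskal_wallis(xs))
      if (length(ok) >= 2) {
        cmb <- utils::combn(ok, 2)
        for (j in seq_len(ncol(cmb))) {
          g1 <- cmb[1, j]; g2 <- cmb[2, j]
          pairwise[[length(pairwise) + 1]] <-
            tag(mann_whitney_u(xs[[g1]], xs[[g2]]), g1 = g1, g2 = g2)
        }
      }
    }
    # paired C3 vs C4 within each group
    for (g in groups) {
      sub <- eri[eri$group == g & eri$band == band &
                   eri$channel %in% c("C3", "C4"), ]
      wide <- stats::reshape(sub[, c("subject_id", "channel", "eri_db")],
                             idvar = "subject_id", timevar = "channel",
                             direction = "wide")
      wide <- wide[stats::complete.cases(wide), ]
      if (nrow(wide) < min_n) { next }
      row <- wilcoxon_signed_rank(wide$eri_db.C3, wide$eri_db.C4)
      row$channel <- "C3-C4"; row$band <- band; row$group1 <- g
      paired[[length(paired) + 1]] <- row
    }
    # lateralization index comparisons
    if (!is.null(li)) {
      ls <- lapply(groups, function(g)
        stats::na.omit(grab(li, "li", group = g, band = band)))
      names(ls) <- groups
      ls <- ls[usable(ls)]
      if (length(ls) >= 2) {
        row <- kruskal_wallis(ls); row$band <- band
        li_omni[[length(li_omni) + 1]] <- row
        cmb <- utils::combn(names(ls), 2)
        for (j in seq_len(ncol(cmb))) {
          g1 <- cmb[1, j]; g2 <- cmb[2, j]
          row <- mann_whitney_u(ls[[g1]], ls[[g2]])
          row$band <- band; row$group1 <- g1; row$group2 <- g2
          li_pw[[length(li_pw) + 1]] <- row
        }
      }
    }
  }
  demo <- list()
  if (!is.null(demographics)) {
    for (nm in names(demographics)) {
      row <- chi_square_independence(demographics[[nm]])
      row$test <- paste0("chi_square_", nm)
      demo[[length(demo) + 1]] <- row
    }
  }
  bindr <- function(lst) if (length(lst)) do.call(rbind, lapply(lst, function(d) {
    for (col in c("channel", "band", "group1", "group2"))
      if (is.null(d[[col]])) d[[col]] <- NA_character_
    d
  })) else NULL
  out <- list(screens = bindr(screens), omnibus = bindr(omnibus),
              pairwise = bindr(pairwise), paired_c3_c4 = bindr(paired),
              li_omnibus = bindr(li_omni), li_pairwise = bindr(li_pw),
              demographics = bindr(demo))
  if (correction != "none") {
    for (nm in c("pairwise", "li_pairwise"))
      if (!is.null(out[[nm]]))
        out[[nm]]$p_adjusted <- stats::p.adjust(out[[nm]]$p_value,
                                                method = correction)
  }
  out
}
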