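# Region-versus-rest differential expression with optional empirical-Bayes
# variance moderation. The moderation shrinks per-gene pooled variances toward
# a common prior estimated by method of moments on the log sample variances
# (the scaled inverse chi-square hierarchical model behind moderated t
# statistics), so ordering information is borrowed across genes when
# per-group sample sizes are small.

# Invert the trigamma function by Newton iteration on 1/trigamma, which is
# nearly linear; converges in a handful of steps for any positive input.
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(-dif / y) < 1e-8) break
  }
  y
}

#' Estimate the variance prior by method of moments
#'
#' Fits the scaled inverse chi-square prior for gene-wise variances: given
#' sample variances `s2` on `df` degrees of freedom each, the log variances
#' (corrected for the chi-square log-moments) have mean
#' `log(s0^2) + digamma(d0/2) - log(d0/2)` and excess variance
#' `trigamma(d0/2)`; matching those two moments yields the prior degrees of
#' freedom `d0` and prior variance `s0^2`. Zero excess variance gives
#' `prior_df = Inf` (all gene variances shrunk to the common value).
#'
#' @param s2 numeric vector of positive sample variances.
#' @param df residual degrees of freedom of each variance (scalar).
#' @return list with `prior_df` and `prior_var`.
#' @export
estimate_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) stop("need at least 2 positive variances")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    prior_df <- 2 * trigamma_inverse(evar)
    prior_var <- exp(mean(e) + digamma(prior_df / 2) - log(prior_df / 2))
  } else {
    prior_df <- Inf
    prior_var <- exp(mean(e))
  }
  list(prior_df = prior_df, prior_var = prior_var)
}

#' Shrink gene-wise variances toward the prior
#'
#' Posterior mean of each variance under the inverse chi-square prior:
#' `(prior_df * prior_var + df * s2) / (prior_df + df)`. With
#' `prior_df = Inf` every moderated variance equals `prior_var`; with
#' `prior_df = 0` the variances are returned unchanged (so the moderated t
#' reduces to the ordinary t).
#'
#' @param s2 numeric vector of sample variances.
#' @param df residual degrees of freedom of each variance.
#' @param prior_df,prior_var prior degrees of freedom and variance, e.g. from
#'   [estimate_variance_prior()].
#' @return numeric vector of moderated variances.
#' @export
squeeze_var <- function(s2, df, prior_df, prior_var) {
  if (is.infinite(prior_df)) return(rep(prior_var, length(s2)))
  (prior_df * prior_var + df * s2) / (prior_df + df)
}

#' Region-versus-rest expression contrast
#'
#' For every gene, contrasts the samples of one brain region against all
#' other samples pooled. Linear-scale studies are log2-transformed (with a
#' pseudocount) first, so the contrast is a log2 fold change in either case.
#' With `moderation = "eb"` the per-gene pooled variances are shrunk with
#' [squeeze_var()] using a prior fitted by [estimate_variance_prior()] and the
#' t statistic is referred to `df + prior_df` degrees of freedom;
#' `moderation = "plain"` is the ordinary pooled two-sample t. A gene is
#' flagged highly expressed in the region when its expression is at least one
#' time (100%) higher than the average of the other regions -- fold change
#' >= 2, i.e. log2 difference >= 1, boundary inclusive -- and the two-sided
#' p-value is below `alpha`.
#'
#' @param study an [expression_study()].
#' @param region region name present in the study; both the region and its
#'   complement must have at least 2 samples.
#' @param alpha significance cutoff for the flag (default 0.05).
#' @param moderation `"eb"` (moderated t, default) or `"plain"`.
#' @param fold_threshold linear fold-change threshold for the flag
#'   (default 2).
#' @param pseudocount added before log2 transform of linear-scale values.
#' @param out_mean `"pooled"` (default): mean over all non-region samples
#'   pooled; `"mean_of_means"`: mean of the other regions' means.
#' @return data frame with one row per gene: `gene`, `region`, `mean_in`,
#'   `mean_out` (log2 scale), `log2_fc`, `fold`, `t_stat`, `df`, `p_value`,
#'   `high_flag`.
#' @export
region_contrast <- function(study, region, alpha = 0.05,
                            moderation = c("eb", "plain"),
                            fold_threshold = 2, pseudocount = 1,
                            out_mean = c("pooled", "mean_of_means")) {
  stopifnot(inherits(study, "expression_study"))
  moderation <- match.arg(moderation)
  out_mean <- match.arg(out_mean)
  if (!region %in% study$regions) stop("unknown region: ", region)

  x <- study$values
  if (study$scale == "linear") x <- log2(x + pseudocount)
  inn <- study$region_of == region
  n1 <- sum(inn); n2 <- sum(!inn)
  if (n1 < 2) stop("region '", region, "' has fewer than 2 samples")
  if (n2 < 2) stop("fewer than 2 samples outside region '", region, "'")

  xi <- x[, inn, drop = FALSE]; xo <- x[, !inn, drop = FALSE]
  mean_in <- rowMeans(xi)
  mean_out_pooled <- rowMeans(xo)
  mean_out <- if (out_mean == "pooled") {
    mean_out_pooled
  } else {
    other <- setdiff(study$regions, region)
    rowMeans(vapply(other, function(r)
      rowMeans(x[, study$region_of == r, drop = FALSE]), numeric(nrow(x))))
  }
  # pooled two-group variance always uses the pooled complement, matching the
  # two-sample model; out_mean only changes the reported contrast
  ss <- rowSums((xi - mean_in)^2) + rowSums((xo - mean_out_pooled)^2)
  df <- n1 + n2 - 2
  s2 <- ss / df

  if (moderation == "eb") {
    prior <- estimate_variance_prior(s2, df)
    s2_used <- squeeze_var(s2, df, prior$prior_df, prior$prior_var)
    df_total <- df + prior$prior_df
  } else {
    s2_used <- s2
    df_total <- df
  }

  diff <- mean_in - mean_out
  se <- sqrt(s2_used * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se == 0, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
  p <- 2 * stats::pt(abs(t_stat), df = df_total, lower.tail = FALSE)
  high <- (diff >= log2(fold_threshold)) & (p < alpha)

  data.frame(
    gene = study$genes, region = region,
    mean_in = mean_in, mean_out = mean_out,
    log2_fc = diff, fold = 2^diff,
    t_stat = t_stat, df = df_total, p_value = p, high_flag = high,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Call per-region highly-expressed gene sets
#'
#' Runs [region_contrast()] for every region and assembles the flagged genes
#' into a [marker_catalog()] (one "marker set" per region, background = all
#' study genes), so downstream enrichment reuses the same machinery as the
#' cell-type analysis. The full per-gene contrast tables are attached as the
#' `"contrasts"` attribute.
#'
#' @inheritParams region_contrast
#' @param ... passed on to [region_contrast()].
#' @return a [marker_catalog()]; `attr(, "contrasts")` holds the row-bound
#'   contrast results for all regions.
#' @export
region_high_sets <- function(study, alpha = 0.05, ...) {
  stopifnot(inherits(study, "expression_study"))
  if (length(study$regions) < 2) stop("need at least 2 regions")
  tabs <- lapply(study$regions, function(r)
    region_contrast(study, r, alpha = alpha, ...))
  sets <- lapply(tabs, function(t) t$gene[t$high_flag])
  names(sets) <- study$regions
  # a region may flag nothing; keep it as an (empty) context
  out <- marker_catalog(lapply(sets, function(g) as.character(g)),
                        background = study$genes)
  attr(out, "contrasts") <- do.call(rbind, tabs)
  out
}
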