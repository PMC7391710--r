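#' Hardy-Weinberg genotype prior from an allele frequency
#'
#' Block genotype priors come from the anchor SNP's minor-allele frequency f
#' under Hardy-Weinberg equilibrium: p(AA) = (1-f)^2, p(AB) = 2f(1-f),
#' p(BB) = f^2. At f = 0.5 this gives the familiar 0.25 / 0.5 / 0.25.
#'
#' @param maf Minor-allele frequency in (0, 0.5].
#' @return Named numeric vector `c(AA =, AB =, BB =)`.
#' @export
genotype_prior <- function(maf) {
  stopifnot(maf > 0, maf <= 0.5)
  c(AA = (1 - maf)^2, AB = 2 * maf * (1 - maf), BB = maf^2)
}

#' Scoring configuration
#'
#' @param prior_odds Prior odds of no-swap versus swap, p(s=0)/p(s=1)
#'   (default 1, the conservative choice). A different prior shifts the
#'   total LOD by the constant log10(prior_odds).
#' @param cap_sigma Lower cap on any single block's log10 contribution
#'   (default -3), guarding the cumulative score against single-locus
#'   artifacts; a base-calling error rate around 1e-3 motivates the value.
#' @param decision_threshold |LOD| bound for a conclusive call (default 5):
#'   LOD >= threshold is a donor match, LOD <= -threshold a donor mismatch,
#'   anything between is inconclusive.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(prior_odds = 1, cap_sigma = -3,
                           decision_threshold = 5) {
  stopifnot(prior_odds > 0, cap_sigma < 0, decision_threshold > 0)
  structure(list(prior_odds = prior_odds, cap_sigma = cap_sigma,
                 decision_threshold = decision_threshold),
            class = "scoring_config")
}

# log10 of sum(10^x) for rows of a matrix, stable; rows of all -Inf -> -Inf.
row_log10_sum_exp <- function(x) {
  m <- do.call(pmax, c(as.data.frame(x), na.rm = TRUE))
  out <- m + log10(rowSums(10^(x - m)))
  out[!is.finite(m)] <- -Inf
  out
}

#' Capped per-block LOD contribution
#'
#' For one LD block with log10 genotype likelihoods `lx`, `ly` (order AA,
#' AB, BB) in the two datasets and Hardy-Weinberg prior p, the block's
#' log10-odds of shared versus distinct genetic origin is
#' \deqn{\log_{10} \frac{\sum_\theta L_x(\theta) L_y(\theta) p(\theta)}
#'   {\sum_\theta L_x(\theta) p(\theta)\; \sum_\varphi L_y(\varphi) p(\varphi)},}
#' computed stably in log space and floored at `cap_sigma`. A block where
#' either dataset has no observations has likelihoods (1,1,1) on the linear
#' scale, for which the ratio is identically 1; such blocks contribute
#' exactly 0.
#'
#' @param lx,ly Numeric length-3 log10 likelihood vectors (AA, AB, BB), or
#'   matrices with 3 columns for many blocks at once.
#' @param prior Length-3 prior vector from [genotype_prior()], or a matrix
#'   with one row per block.
#' @param cap_sigma Per-block floor (default -3).
#' @return Capped log10 contribution(s), each at least `cap_sigma`.
#' @export
block_lod_term <- function(lx, ly, prior, cap_sigma = -3) {
  if (!is.matrix(lx)) lx <- matrix(lx, nrow = 1)
  if (!is.matrix(ly)) ly <- matrix(ly, nrow = 1)
  if (!is.matrix(prior)) prior <- matrix(prior, nrow = nrow(lx), ncol = 3,
                                         byrow = TRUE)
  lp <- log10(prior)
  num <- row_log10_sum_exp(lx + ly + lp)
  den <- row_log10_sum_exp(lx + lp) + row_log10_sum_exp(ly + lp)
  term <- num - den
  # a side with no data has lx = (0,0,0): the ratio is analytically 1
  no_data <- rowSums(lx != 0) == 0L | rowSums(ly != 0) == 0L
  term[no_data] <- 0
  pmax(term, cap_sigma)
}

#' Genome-wide capped LOD between two fingerprints
#'
#' Sums the capped per-block contributions over all blocks of the map the
#' fingerprints are bound to and adds the constant prior shift
#' log10(prior_odds). A positive LOD is evidence that the datasets share a
#' donor; a negative LOD is evidence of a swap; scores in
#' (-threshold, threshold) are inconclusive and typically reflect low
#' coverage or poor overlap with the map.
#'
#' @param fx,fy `fingerprint` objects bound to the same map (checksums must
#'   match).
#' @param map The `haplotype_map` both fingerprints were extracted with.
#' @param cfg A `scoring_config`.
#' @return An object of class `lod_report`: list with `lod`, `per_block`
#'   (data.frame of anchor, term, informative flag), `n_informative`
#'   (blocks where both sides have observations), `classification`, and the
#'   two sample ids.
#' @export
total_lod <- function(fx, fy, map, cfg = scoring_config()) {
  stopifnot(inherits(fx, "fingerprint"), inherits(fy, "fingerprint"))
  chk <- map_checksum(map)
  if (!identical(fx$map_checksum, chk) || !identical(fy$map_checksum, chk)) {
    stop("fingerprints are not bound to the supplied map (checksum mismatch)")
  }
  anchors <- map_anchors(map)
  bx <- fx$blocks[match(anchors$name, fx$blocks$anchor), , drop = FALSE]
  by <- fy$blocks[match(anchors$name, fy$blocks$anchor), , drop = FALSE]
  maf <- pmin(pmax(anchors$maf, 1e-6), 0.5)  # guard degenerate stored MAF
  prior <- cbind((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  lx <- as.matrix(bx[, c("ll_AA", "ll_AB", "ll_BB")])
  ly <- as.matrix(by[, c("ll_AA", "ll_AB", "ll_BB")])
  term <- block_lod_term(lx, ly, prior, cfg$cap_sigma)
  informative <- bx$n_obs > 0L & by$n_obs > 0L
  lod <- sum(term) + log10(cfg$prior_odds)
  structure(list(lod = lod,
                 per_block = data.frame(anchor = anchors$name, term = term,
                                        informative = informative,
                                        stringsAsFactors = FALSE),
                 n_informative = sum(informative),
                 classification = classify(lod, cfg$decision_threshold),
                 left_sample = fx$sample_id, right_sample = fy$sample_id),
            class = "lod_report")
}

#' @export
print.lod_report <- function(x, ...) {
  cat(sprintf("LOD(%s, %s) = %.3f [%s], %d informative blocks\n",
              x$left_sample, x$right_sample, x$lod, x$classification,
              x$n_informative))
  invisible(x)
}

#' Shift a LOD score for a non-default prior
#'
#' A prior odds q of no-swap versus swap shifts the LOD by the constant
#' log10(q); the shift is exact.
#'
#' @param lod LOD score(s) computed with prior odds 1.
#' @param prior_odds Positive prior odds ratio.
#' @return Shifted score(s).
#' @export
shift_for_prior <- function(lod, prior_odds) {
  if (!is.numeric(prior_odds) || any(prior_odds <= 0)) {
    stop("prior_odds must be positive")
  }
  lod + log10(prior_odds)
}

#' Classify a LOD score
#'
#' @param lod LOD score(s).
#' @param threshold Positive decision bound (default 5). Scores exactly at
#'   the bound are conclusive.
#' @return `"MATCH"`, `"MISMATCH"` or `"INCONCLUSIVE"` (vectorized).
#' @export
classify <- function(lod, threshold = 5) {
  stopifnot(threshold > 0)
  ifelse(lod >= threshold, "MATCH",
         ifelse(lod <= -threshold, "MISMATCH", "INCONCLUSIVE"))
}
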