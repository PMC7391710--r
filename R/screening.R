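#' Self-LOD of a fingerprint
#'
#' The LOD of a dataset compared against itself. It is always nonnegative
#' (Jensen: sum p q^2 >= (sum p q)^2) and grows with the dataset's
#' informative overlap with the haplotype map, so it ranks candidates for
#' the representative set of a donor.
#'
#' @param fp A `fingerprint`.
#' @param map The bound `haplotype_map`.
#' @param cfg A `scoring_config`.
#' @return Nonnegative score.
#' @export
self_lod <- function(fp, map, cfg = scoring_config()) {
  total_lod(fp, fp, map, cfg)$lod
}

#' Select three self-consistent representative datasets for a donor
#'
#' Candidates are ranked by self-LOD (ties broken by sample id for
#' determinism) and the top three form the provisional representative set.
#' Self-consistency requires all three pairwise LODs to be at least the
#' decision threshold. The single-swap pattern — one member scoring at or
#' below the negative threshold against both others while the remaining
#' pair is consistent — is repaired automatically by replacing that member
#' with the next-highest self-LOD candidate and re-checking. Any other
#' inconsistency pattern, or an exhausted candidate pool, yields a
#' MANUAL_REVIEW outcome.
#'
#' @param donor_fps Named list of `fingerprint`s (names are dataset ids) for
#'   one nominal donor; at least 4 so that replacement is possible.
#' @param map The bound `haplotype_map`.
#' @param cfg A `scoring_config`.
#' @return List with `status` (`"OK"` or `"MANUAL_REVIEW"`),
#'   `representatives` (named list of 3 fingerprints), `replaced` (dataset
#'   ids swapped out during repair) and `self_lods`.
#' @export
select_representatives <- function(donor_fps, map, cfg = scoring_config()) {
  if (length(donor_fps) < 4L) {
    stop("representative selection requires at least 4 datasets per donor")
  }
  ids <- names(donor_fps)
  if (is.null(ids) || anyDuplicated(ids)) stop("donor_fps must be uniquely named")
  sl <- vapply(donor_fps, self_lod, numeric(1), map = map, cfg = cfg)
  ord <- ids[order(-sl, ids, method = "radix")]
  trip <- ord[1:3]
  pool <- ord[-(1:3)]
  replaced <- character()
  thr <- cfg$decision_threshold

  repeat {
    lods <- pair_lods(donor_fps[trip], map, cfg)
    if (all(lods >= thr)) {
      return(list(status = "OK", representatives = donor_fps[trip],
                  replaced = replaced, self_lods = sl))
    }
    bad <- single_swap_member(trip, lods, thr)
    if (is.na(bad) || !length(pool)) {
      return(list(status = "MANUAL_REVIEW", representatives = donor_fps[trip],
                  replaced = replaced, self_lods = sl))
    }
    replaced <- c(replaced, bad)
    trip[trip == bad] <- pool[[1]]
    pool <- pool[-1]
  }
}

# pairwise LODs of a 3-member set, named "a|b"
pair_lods <- function(fps, map, cfg) {
  ids <- names(fps)
  pairs <- utils::combn(ids, 2)
  setNames(apply(pairs, 2, function(p) {
    total_lod(fps[[p[1]]], fps[[p[2]]], map, cfg)$lod
  }), apply(pairs, 2, paste, collapse = "|"))
}

# the one member with both its pairwise LODs <= -thr while the opposite pair
# is consistent (>= thr); NA when the pattern does not match
single_swap_member <- function(trip, lods, thr) {
  ends <- strsplit(names(lods), "|", fixed = TRUE)
  for (m in trip) {
    mine <- vapply(ends, function(p) m %in% p, logical(1))
    if (sum(mine) == 2L && all(lods[mine] <= -thr) && all(lods[!mine] >= thr)) {
      return(m)
    }
  }
  NA_character_
}

#' Screen a dataset manifest for sample swaps
#'
#' Per donor with at least 4 datasets, selects three representatives
#' ([select_representatives()]) and compares every other dataset of that
#' donor against them: any LOD at or below the negative threshold flags the
#' dataset as a swap (flagging takes precedence), otherwise any LOD inside
#' the inconclusive band marks it inconclusive, otherwise it is confirmed.
#' Flagged datasets are compared against every donor's representatives to
#' nominate a true donor, and representative sets are cross-compared to
#' detect duplicate donors. The comparison count scales linearly with the
#' number of datasets (3 per screened dataset plus representative upkeep).
#'
#' @param manifest Data.frame with columns `dataset_id` (unique) and `donor`.
#' @param fingerprints Named list of `fingerprint`s covering all dataset ids.
#' @param map The bound `haplotype_map`.
#' @param cfg A `scoring_config`.
#' @return An object of class `screening_report`: list with `results`
#'   (data.frame: dataset_id, donor, status, min_lod_vs_reps,
#'   nominated_donor), `representatives` (per donor), `donor_clusters`
#'   (duplicate-donor clusters from [cross_donor_check()]), and
#'   `n_comparisons`.
#' @export
screen <- function(manifest, fingerprints, map, cfg = scoring_config()) {
  stopifnot(all(c("dataset_id", "donor") %in% names(manifest)),
            !anyDuplicated(manifest$dataset_id),
            all(manifest$dataset_id %in% names(fingerprints)))
  thr <- cfg$decision_threshold
  res <- data.frame(dataset_id = manifest$dataset_id, donor = manifest$donor,
                    status = NA_character_, min_lod_vs_reps = NA_real_,
                    nominated_donor = NA_character_, stringsAsFactors = FALSE)
  reps_by_donor <- list()
  n_cmp <- 0L

  for (donor in unique(manifest$donor)) {
    ids <- manifest$dataset_id[manifest$donor == donor]
    if (length(ids) < 4L) {
      res$status[res$dataset_id %in% ids] <- "UNSCREENABLE"
      next
    }
    sel <- select_representatives(fingerprints[ids], map, cfg)
    n_cmp <- n_cmp + 3L + 3L * length(sel$replaced)
    if (sel$status == "MANUAL_REVIEW") {
      res$status[res$dataset_id %in% ids] <- "MANUAL_REVIEW"
      next
    }
    reps_by_donor[[donor]] <- sel$representatives
    rep_ids <- names(sel$representatives)
    res$status[res$dataset_id %in% rep_ids] <- "CONFIRMED"
    for (id in setdiff(ids, rep_ids)) {
      lods <- vapply(sel$representatives, function(r) {
        total_lod(fingerprints[[id]], r, map, cfg)$lod
      }, numeric(1))
      n_cmp <- n_cmp + 3L
      res$min_lod_vs_reps[res$dataset_id == id] <- min(lods)
      res$status[res$dataset_id == id] <-
        if (any(lods <= -thr)) "SWAP_FLAGGED"
        else if (any(lods > -thr & lods < thr)) "INCONCLUSIVE"
        else "CONFIRMED"
    }
  }

  flagged <- res$dataset_id[!is.na(res$status) & res$status == "SWAP_FLAGGED"]
  for (id in flagged) {
    nom <- nominate_donor(fingerprints[[id]], reps_by_donor, map, cfg,
                          exclude = res$donor[res$dataset_id == id])
    n_cmp <- n_cmp + 3L * length(reps_by_donor)
    if (nrow(nom)) {
      res$nominated_donor[res$dataset_id == id] <- nom$donor[[1]]
    }
  }

  clusters <- cross_donor_check(reps_by_donor, map, cfg)
  n_cmp <- n_cmp + choose(length(reps_by_donor), 2)

  structure(list(results = res, representatives = reps_by_donor,
                 donor_clusters = clusters, n_comparisons = n_cmp),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("screening_report:\n")
  print(table(x$results$status))
  if (length(x$donor_clusters)) {
    cat(sprintf("duplicate-donor clusters: %d\n", length(x$donor_clusters)))
  }
  invisible(x)
}

#' Nominate the true donor of a flagged dataset
#'
#' A donor qualifies when the flagged fingerprint scores at or above the
#' decision threshold against all of that donor's representatives.
#' Qualifying donors are ranked by their minimum LOD, highest first, so
#' duplicate donors (the same true individual accessioned twice) are all
#' reported.
#'
#' @param flagged_fp The flagged `fingerprint`.
#' @param reps_by_donor Named list (by donor) of representative fingerprint
#'   lists.
#' @param map The bound `haplotype_map`.
#' @param cfg A `scoring_config`.
#' @param exclude Optional donor name(s) to skip (the nominal donor).
#' @return Data.frame with columns `donor` and `min_lod`, ranked; zero rows
#'   when no donor qualifies.
#' @export
nominate_donor <- function(flagged_fp, reps_by_donor, map,
                           cfg = scoring_config(), exclude = NULL) {
  thr <- cfg$decision_threshold
  rows <- list()
  for (donor in setdiff(names(reps_by_donor), exclude)) {
    lods <- vapply(reps_by_donor[[donor]], function(r) {
      total_lod(flagged_fp, r, map, cfg)$lod
    }, numeric(1))
    if (all(lods >= thr)) {
      rows[[donor]] <- data.frame(donor = donor, min_lod = min(lods),
                                  stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(donor = character(), min_lod = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(-out$min_lod, out$donor, method = "radix"), , drop = FALSE]
}

#' Detect duplicate donors among representative sets
#'
#' Compares representatives across nominal donors; two donors are linked
#' when any cross-donor representative pair scores a conclusive positive
#' LOD. Connected components (single linkage) of size greater than one are
#' duplicate-donor clusters.
#'
#' @param reps_by_donor Named list (by donor) of representative fingerprint
#'   lists.
#' @param map The bound `haplotype_map`.
#' @param cfg A `scoring_config`.
#' @return List of character vectors, each a cluster of donor names.
#' @export
cross_donor_check <- function(reps_by_donor, map, cfg = scoring_config()) {
  donors <- names(reps_by_donor)
  n <- length(donors)
  if (n < 2L) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  thr <- cfg$decision_threshold
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (find(i) == find(j)) next
      linked <- FALSE
      for (ri in reps_by_donor[[i]]) {
        for (rj in reps_by_donor[[j]]) {
          if (total_lod(ri, rj, map, cfg)$lod >= thr) { linked <- TRUE; break }
        }
        if (linked) break
      }
      if (linked) parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(donors, roots)
  unname(comps[lengths(comps) > 1L])
}

#' LOD as a function of contamination fraction
#'
#' Mixes reads from a reference-donor dataset with reads from an unrelated
#' donor at each requested fraction, fingerprints each mixture and scores it
#' against a clean reference fingerprint. At fraction 0 the LOD equals the
#' uncontaminated same-donor score (up to resampling noise); as the
#' contaminant fraction grows the LOD decreases, crossing into mismatch
#' territory at high contamination.
#'
#' @param reads_a Read set from the reference donor.
#' @param reads_b Read set from an unrelated donor.
#' @param reference_fp Clean `fingerprint` of the reference donor.
#' @param map The bound `haplotype_map`.
#' @param fractions Contaminant fractions in \[0, 1\] (default 0 to 1 by 0.1).
#' @param total_reads Reads per mixture (default: size of the smaller pool).
#' @param seed Integer seed; the profile is reproducible.
#' @param filters A `read_filter_config`.
#' @param cfg A `scoring_config`.
#' @return Data.frame with columns `fraction`, `lod`, `n_informative`.
#' @export
contamination_profile <- function(reads_a, reads_b, reference_fp, map,
                                  fractions = seq(0, 1, by = 0.1),
                                  total_reads = NULL, seed = 1L,
                                  filters = read_filter_config(),
                                  cfg = scoring_config()) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  if (is.null(total_reads)) total_reads <- min(nrow(reads_a), nrow(reads_b))
  out <- data.frame(fraction = fractions, lod = NA_real_,
                    n_informative = NA_integer_)
  set.seed(seed)
  for (k in seq_along(fractions)) {
    q <- fractions[[k]]
    n_b <- round(q * total_reads)
    n_a <- total_reads - n_b
    if (n_a > nrow(reads_a) || n_b > nrow(reads_b)) {
      stop(sprintf("insufficient reads for fraction %.2f (need %d + %d)",
                   q, n_a, n_b))
    }
    mix <- rbind(
      reads_a[sample.int(nrow(reads_a), n_a), , drop = FALSE],
      reads_b[sample.int(nrow(reads_b), n_b), , drop = FALSE])
    fp <- build_fingerprint(mix, map, filters,
                            sample_id = sprintf("mix_%0.2f", q))
    rep <- total_lod(fp, reference_fp, map, cfg)
    out$lod[[k]] <- rep$lod
    out$n_informative[[k]] <- rep$n_informative
  }
  out
}
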