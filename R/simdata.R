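#' Population model for synthetic phased panels
#'
#' Describes the LD world the haplotype map assumes: independent blocks,
#' each an anchor SNP plus members that copy the anchor's allele on every
#' haplotype except for a small per-site switch probability (which controls
#' the within-block r-squared; a switch rate of 0.02 keeps member-anchor
#' r-squared above 0.85 for the vast majority of members at realistic panel
#' sizes). Distinct blocks are generated independently, so cross-block
#' r-squared is at sampling-noise level.
#'
#' @param n_blocks Number of LD blocks (default 1000).
#' @param snps_per_block Fixed member count per block including the anchor
#'   (default 5), or a function(n_blocks) returning counts. The default
#'   matches the LD-pruning slide (5 SNPs), so that every within-block pair
#'   falls inside an examined pruning window even at synthetic SNP
#'   densities far sparser than a real genotype panel.
#' @param maf_sampler Function(n) drawing anchor minor-allele frequencies
#'   (default uniform on \[0.15, 0.5\]). The floor keeps the generated world
#'   consistent with the block definition: with a 2% switch rate, blocks
#'   anchored below MAF of about 0.14 would systematically violate the
#'   within-block r-squared >= 0.85 assumption the map relies on.
#' @param within_block_switch_rate Per-site probability that a member
#'   haplotype allele differs from the anchor's (default 0.02).
#' @param n_haplotypes Haplotype count, two per individual (default 200).
#' @param inter_block_spacing_bp Distance between consecutive block starts
#'   (default 20,000).
#' @param intra_block_spacing_bp Distance between SNPs inside a block
#'   (default 300, larger than a read so single reads usually cover one
#'   SNP).
#' @param chrom Contig name (default "sim1").
#' @param n_populations Number of population labels to assign (default 1).
#' @param seed Integer seed.
#' @return A list of class `population_model`.
#' @export
population_model <- function(n_blocks = 1000L, snps_per_block = 5L,
                             maf_sampler = function(n) runif(n, 0.15, 0.5),
                             within_block_switch_rate = 0.02,
                             n_haplotypes = 200L,
                             inter_block_spacing_bp = 20000L,
                             intra_block_spacing_bp = 300L,
                             chrom = "sim1", n_populations = 1L, seed = 1L) {
  stopifnot(n_blocks >= 1, n_haplotypes >= 2, n_haplotypes %% 2 == 0,
            within_block_switch_rate >= 0, within_block_switch_rate < 0.5,
            inter_block_spacing_bp > 0, intra_block_spacing_bp > 0)
  structure(list(n_blocks = as.integer(n_blocks),
                 snps_per_block = snps_per_block,
                 maf_sampler = maf_sampler,
                 within_block_switch_rate = within_block_switch_rate,
                 n_haplotypes = as.integer(n_haplotypes),
                 inter_block_spacing_bp = as.integer(inter_block_spacing_bp),
                 intra_block_spacing_bp = as.integer(intra_block_spacing_bp),
                 chrom = chrom, n_populations = as.integer(n_populations),
                 seed = as.integer(seed)),
            class = "population_model")
}

#' Simulate a phased panel with block LD structure
#'
#' Anchor alleles are drawn per haplotype at the block's MAF; members copy
#' the anchor with the model's switch probability. Columns whose minor
#' allele ends up more frequent than 0.5 are relabeled (indicator flipped,
#' major/minor swapped), which is how negative-phase members arise near
#' MAF 0.5. The generative recipe (block assignment, per-column relabeling,
#' model MAF) is stored as an attribute so that fresh, unrelated haplotypes
#' can later be drawn from the same population.
#'
#' @param model A `population_model`.
#' @return A `phased_panel` whose `snps` carry a `block` column; attributes
#'   `model` and `truth` record the generative structure.
#' @export
simulate_panel <- function(model) {
  set.seed(model$seed)
  nb <- model$n_blocks
  sizes <- if (is.function(model$snps_per_block)) {
    pmax(1L, as.integer(model$snps_per_block(nb)))
  } else rep(as.integer(model$snps_per_block), nb)
  maf <- model$maf_sampler(nb)
  nh <- model$n_haplotypes
  s <- model$within_block_switch_rate

  n_snp <- sum(sizes)
  H <- matrix(0, nrow = nh, ncol = n_snp)
  block_id <- integer(n_snp)
  is_anchor <- logical(n_snp)
  flip <- logical(n_snp)
  pos <- integer(n_snp)
  col <- 0L
  for (b in seq_len(nb)) {
    a <- rbinom(nh, 1L, maf[[b]])
    start <- (b - 1L) * model$inter_block_spacing_bp + 1L
    for (k in seq_len(sizes[[b]])) {
      col <- col + 1L
      v <- if (k == 1L) a else {
        sw <- runif(nh) < s
        ifelse(sw, 1 - a, a)
      }
      fl <- mean(v) > 0.5
      H[, col] <- if (fl) 1 - v else v
      block_id[[col]] <- b
      is_anchor[[col]] <- k == 1L
      flip[[col]] <- fl
      pos[[col]] <- start + (k - 1L) * model$intra_block_spacing_bp
    }
  }
  name <- sprintf("b%05d_s%d", block_id, stats::ave(block_id, block_id,
                                                    FUN = seq_along))
  bases <- t(vapply(seq_len(n_snp), function(i) sample(VALID_BASES, 2L),
                    character(2)))
  snps <- data.frame(chrom = model$chrom, pos = pos, name = name,
                     major = bases[, 1], minor = bases[, 2],
                     block = block_id, stringsAsFactors = FALSE)
  populations <- if (model$n_populations > 1L) {
    rep_len(sprintf("POP%d", seq_len(model$n_populations)), nh / 2L)
  } else NULL
  panel <- phased_panel(snps, H, populations)
  attr(panel, "model") <- model
  attr(panel, "truth") <- data.frame(
    name = name, block = block_id, is_anchor = is_anchor, flip = flip,
    block_maf = maf[block_id], stringsAsFactors = FALSE)
  panel
}

#' Planted-truth haplotype map of a simulated panel
#'
#' Builds the haplotype map directly from the generator's block structure
#' instead of re-estimating it with the map builder: every simulated block
#' becomes one map block, member phase comes from the recorded relabeling
#' (a member is negative-phase when its 0/1 coding was flipped relative to
#' its anchor's), and MAFs are the panel's empirical frequencies. This is
#' the fast, exact map for planted-truth experiments; [build_map()] is the
#' estimator under test.
#'
#' @param panel A `phased_panel` from [simulate_panel()].
#' @return A `haplotype_map`.
#' @export
map_from_panel <- function(panel) {
  truth <- attr(panel, "truth")
  if (is.null(truth)) stop("panel has no recorded block structure; use build_map()")
  snps <- panel$snps
  anchor_of_block <- truth$name[truth$is_anchor]
  anchor_flip <- truth$flip[truth$is_anchor]
  b <- truth$block
  haplotype_map(data.frame(
    chrom = snps$chrom, pos = snps$pos, name = snps$name,
    major = snps$major, minor = snps$minor,
    maf = round(pmin(snps$maf, 0.5), 6),
    anchor = anchor_of_block[b],
    phase = ifelse(truth$flip == anchor_flip[b], "+", "-"),
    stringsAsFactors = FALSE))
}

# n fresh haplotypes: generative draw when the panel records its model,
# otherwise resampled panel rows
draw_haplotypes <- function(panel, n) {
  truth <- attr(panel, "truth")
  model <- attr(panel, "model")
  if (is.null(truth) || is.null(model)) {
    idx <- sample.int(nrow(panel$haplotypes), n, replace = TRUE)
    return(panel$haplotypes[idx, , drop = FALSE])
  }
  s <- model$within_block_switch_rate
  H <- matrix(0, nrow = n, ncol = nrow(panel$snps))
  for (b in unique(truth$block)) {
    cols <- which(truth$block == b)
    a <- rbinom(n, 1L, truth$block_maf[[cols[1]]])
    for (cc in cols) {
      v <- if (truth$is_anchor[[cc]]) a else {
        sw <- runif(n) < s
        ifelse(sw, 1 - a, a)
      }
      H[, cc] <- if (truth$flip[[cc]]) 1 - v else v
    }
  }
  colnames(H) <- panel$snps$name
  H
}

#' Sample a diploid individual from a panel's population
#'
#' @param panel A `phased_panel` (from [simulate_panel()] for generative
#'   draws; otherwise haplotypes are resampled from the panel rows).
#' @param relationship `"unrelated"` (default), `"parent_child"`,
#'   `"siblings"` or `"duplicate_donor"`.
#' @param parents For `"parent_child"`, a list with the one parent; for
#'   `"siblings"`, a list of the two parents (a sibling is one child of the
#'   pair; call again for another sibling); for `"duplicate_donor"`, a list
#'   with the individual to duplicate.
#' @param id Identifier for the new individual.
#' @param seed Optional integer seed.
#' @return An object of class `sim_individual`: list with `id` and `hap`, a
#'   2 x n_snps allele-indicator matrix. Transmission is per LD block with
#'   no recombination within a block.
#' @export
sample_individual <- function(panel,
                              relationship = c("unrelated", "parent_child",
                                               "siblings", "duplicate_donor"),
                              parents = NULL, id = "ind", seed = NULL) {
  relationship <- match.arg(relationship)
  if (!is.null(seed)) set.seed(seed)
  blocks <- panel_block_ids(panel)
  hap <- switch(
    relationship,
    unrelated = draw_haplotypes(panel, 2L),
    duplicate_donor = {
      if (length(parents) != 1L) stop("duplicate_donor requires the one individual to duplicate")
      parents[[1]]$hap
    },
    parent_child = {
      if (length(parents) != 1L) stop("parent_child requires one parent")
      rbind(transmit(parents[[1]]$hap, blocks), draw_haplotypes(panel, 1L))
    },
    siblings = {
      if (length(parents) != 2L) stop("siblings requires two parents")
      rbind(transmit(parents[[1]]$hap, blocks),
            transmit(parents[[2]]$hap, blocks))
    })
  rownames(hap) <- NULL
  colnames(hap) <- panel$snps$name
  structure(list(id = id, hap = hap), class = "sim_individual")
}

panel_block_ids <- function(panel) {
  if (!is.null(panel$snps$block)) return(panel$snps$block)
  seq_len(nrow(panel$snps))  # no block structure: every SNP its own block
}

# one gamete: per block, one of the parent's two haplotypes, whole
transmit <- function(parent_hap, blocks) {
  ub <- unique(blocks)
  pick <- sample(c(1L, 2L), length(ub), replace = TRUE)
  choice <- pick[match(blocks, ub)]
  out <- numeric(length(blocks))
  out[choice == 1L] <- parent_hap[1L, choice == 1L]
  out[choice == 2L] <- parent_hap[2L, choice == 2L]
  out
}

#' Assay model for read simulation
#'
#' @param covered_blocks Fraction of map blocks the assay covers (default 1),
#'   or a character vector of anchor names.
#' @param member_subset_rule Which SNPs of a covered block reads may cover:
#'   `"all"`, `"anchor_only"`, `"members_only"`, or an integer vector of
#'   within-block ranks (1 = anchor, 2 = first member, ...). Disjoint
#'   footprints for two assays are obtained with disjoint rank sets.
#' @param depth_lambda Mean per-site coverage, Poisson (default 30).
#' @param base_error_rate Per-base error probability (default 0.001); an
#'   error flips the observed allele to the other allele.
#' @param read_length Read length in bp (default 50).
#' @param mapping_quality Emitted MAPQ (default 60).
#' @param base_quality Emitted base quality (default 30).
#' @param paired Emit read pairs (default FALSE; pairs share a qname).
#' @param frac_duplicate Fraction of extra duplicate-flagged copies added to
#'   exercise the duplicate filter (default 0).
#' @param frac_secondary Fraction of extra secondary-flagged copies
#'   (default 0).
#' @param frac_low_mq Fraction of reads emitted at MAPQ 10, below the filter
#'   (default 0).
#' @param frac_low_bq Fraction of reads emitted at base quality 10, below
#'   the filter (default 0).
#' @return A list of class `assay_model`.
#' @export
assay_model <- function(covered_blocks = 1, member_subset_rule = "all",
                        depth_lambda = 30, base_error_rate = 0.001,
                        read_length = 50L, mapping_quality = 60L,
                        base_quality = 30L, paired = FALSE,
                        frac_duplicate = 0, frac_secondary = 0,
                        frac_low_mq = 0, frac_low_bq = 0) {
  stopifnot(depth_lambda >= 0, base_error_rate > 0, base_error_rate <= 0.5,
            read_length >= 1)
  structure(list(covered_blocks = covered_blocks,
                 member_subset_rule = member_subset_rule,
                 depth_lambda = depth_lambda,
                 base_error_rate = base_error_rate,
                 read_length = as.integer(read_length),
                 mapping_quality = as.integer(mapping_quality),
                 base_quality = as.integer(base_quality),
                 paired = isTRUE(paired),
                 frac_duplicate = frac_duplicate,
                 frac_secondary = frac_secondary,
                 frac_low_mq = frac_low_mq, frac_low_bq = frac_low_bq),
            class = "assay_model")
}

assay_sites <- function(map, assay) {
  anchors <- map_anchors(map)$name
  covered <- if (is.character(assay$covered_blocks)) {
    assay$covered_blocks
  } else if (assay$covered_blocks >= 1) {
    anchors
  } else {
    sample(anchors, max(1L, round(assay$covered_blocks * length(anchors))))
  }
  rows <- which(map$anchor %in% covered)
  rule <- assay$member_subset_rule
  if (identical(rule, "all")) return(rows)
  # within-block rank: anchor first, then members by position
  ord <- rows[order(map$anchor[rows], map$name[rows] != map$anchor[rows],
                    map$pos[rows], method = "radix")]
  rank <- sequence(rle(map$anchor[ord])$lengths)
  sel <- if (identical(rule, "anchor_only")) rank == 1L
         else if (identical(rule, "members_only")) rank > 1L
         else rank %in% rule
  sort(ord[sel])
}

#' Simulate aligned reads over a haplotype map for one individual
#'
#' For every covered map site, a Poisson number of reads is generated; each
#' read picks one of the individual's two chromosomes at random, and at
#' every map SNP the read overlaps it carries that chromosome's allele,
#' flipped to the other allele with the assay's error probability.
#' Non-SNP positions carry reference base `A`. Optional extra
#' duplicate-flagged and secondary-flagged copies exercise the read
#' filters.
#'
#' @param individual A `sim_individual` whose SNP names cover the map's.
#' @param map A `haplotype_map`.
#' @param assay An `assay_model`.
#' @param seed Optional integer seed.
#' @return A read-set data.frame (see [read_alignments()]).
#' @export
simulate_reads <- function(individual, map, assay = assay_model(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(qname = character(), flag = integer(),
                      chrom = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE)
  if (nrow(map) == 0L) return(empty)
  snp_col <- match(map$name, colnames(individual$hap))
  if (anyNA(snp_col)) {
    stop("individual lacks map SNPs: ",
         paste(head(map$name[is.na(snp_col)], 3), collapse = ", "))
  }
  sites <- assay_sites(map, assay)
  if (!length(sites)) return(empty)
  len <- assay$read_length
  n_per_site <- rpois(length(sites), assay$depth_lambda)
  total <- sum(n_per_site)
  if (total == 0L) return(empty)

  focal <- rep(sites, n_per_site)
  offset <- sample.int(len, total, replace = TRUE) - 1L
  start <- pmax(1L, map$pos[focal] - offset)
  hap_pick <- sample(c(1L, 2L), total, replace = TRUE)
  qname <- sprintf("%s_r%07d", individual$id, seq_len(total))

  reads <- data.frame(
    qname = qname, flag = 0L, chrom = map$chrom[focal], pos = start,
    mapq = ifelse(runif(total) < assay$frac_low_mq, 10L,
                  assay$mapping_quality),
    cigar = sprintf("%dM", len),
    seq = strrep("A", len),
    qual = strrep(intToUtf8(assay$base_quality + 33L), len),
    stringsAsFactors = FALSE)
  if (assay$frac_low_bq > 0) {
    low <- runif(total) < assay$frac_low_bq
    reads$qual[low] <- strrep(intToUtf8(10L + 33L), len)
  }

  # place the individual's alleles at every map SNP each read overlaps
  hits_list <- list()
  for (chrom in unique(reads$chrom)) {
    srow <- which(map$chrom == chrom)
    rrow <- which(reads$chrom == chrom)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = map$pos[srow], width = 1L),
      IRanges::IRanges(start = reads$pos[rrow], width = len))
    hits_list[[chrom]] <- data.frame(site = srow[S4Vectors::queryHits(ov)],
                                     read = rrow[S4Vectors::subjectHits(ov)])
  }
  hits <- do.call(rbind, hits_list)
  allele <- individual$hap[cbind(hap_pick[hits$read], snp_col[hits$site])]
  err <- runif(nrow(hits)) < assay$base_error_rate
  allele <- ifelse(err, 1 - allele, allele)
  base <- ifelse(allele == 0, map$major[hits$site], map$minor[hits$site])
  off <- map$pos[hits$site] - reads$pos[hits$read] + 1L

  o <- order(hits$read)
  h_read <- hits$read[o]; h_off <- off[o]; h_base <- base[o]
  rank <- sequence(rle(h_read)$lengths)
  for (r in seq_len(max(rank))) {
    sel <- rank == r
    s <- reads$seq[h_read[sel]]
    substr(s, h_off[sel], h_off[sel]) <- h_base[sel]
    reads$seq[h_read[sel]] <- s
  }

  extra <- list()
  if (assay$frac_duplicate > 0) {
    pick <- which(runif(total) < assay$frac_duplicate)
    if (length(pick)) {
      dup <- reads[pick, , drop = FALSE]
      dup$flag <- bitwOr(dup$flag, FLAG_DUPLICATE)
      dup$qname <- paste0(dup$qname, "_dup")
      extra$dup <- dup
    }
  }
  if (assay$frac_secondary > 0) {
    pick <- which(runif(total) < assay$frac_secondary)
    if (length(pick)) {
      sec <- reads[pick, , drop = FALSE]
      sec$flag <- bitwOr(sec$flag, FLAG_SECONDARY)
      sec$qname <- paste0(sec$qname, "_sec")
      extra$sec <- sec
    }
  }
  out <- rbind(reads, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Generate a planted-truth screening cohort
#'
#' Simulates `n_donors` unrelated individuals, `datasets_per_donor` read
#' sets per donor, plants `n_swaps` label swaps (at most one per affected
#' nominal donor; the true donor is another cohort donor), optionally makes
#' some nominal donors duplicates of others, and fingerprints everything.
#' The returned truth table gives the true donor of every dataset so false
#' flag and false match rates are exactly computable.
#'
#' @param panel A `phased_panel` from [simulate_panel()].
#' @param map The `haplotype_map` to fingerprint against.
#' @param n_donors Number of nominal donors.
#' @param datasets_per_donor Datasets per donor (at least 4 for screening).
#' @param n_swaps Number of planted single-dataset swaps (default 0).
#' @param duplicate_donor_of Optional named character vector: entry
#'   `c(D5 = "D1")` makes nominal donor D5 the same true individual as D1.
#' @param assay An `assay_model`.
#' @param filters A `read_filter_config`.
#' @param seed Integer seed; the cohort is a pure function of it.
#' @return List of class `sim_cohort` with `manifest` (dataset_id, donor),
#'   `fingerprints` (named list), `truth` (dataset_id, nominal_donor,
#'   true_donor) and `individuals` (one per true donor identity).
#' @export
make_cohort <- function(panel, map, n_donors, datasets_per_donor,
                        n_swaps = 0L, duplicate_donor_of = NULL,
                        assay = assay_model(), filters = read_filter_config(),
                        seed = 1L) {
  stopifnot(n_donors >= 1, datasets_per_donor >= 1,
            n_swaps <= n_donors)
  set.seed(seed)
  donors <- sprintf("D%02d", seq_len(n_donors))
  individuals <- list()
  for (d in donors) {
    src <- if (d %in% names(duplicate_donor_of)) duplicate_donor_of[[d]] else NULL
    individuals[[d]] <- if (!is.null(src)) {
      sample_individual(panel, "duplicate_donor",
                        parents = list(individuals[[src]]), id = d)
    } else {
      sample_individual(panel, "unrelated", id = d)
    }
  }

  manifest <- data.frame(
    dataset_id = sprintf("%s_ds%02d", rep(donors, each = datasets_per_donor),
                         rep(seq_len(datasets_per_donor), n_donors)),
    donor = rep(donors, each = datasets_per_donor),
    stringsAsFactors = FALSE)
  truth <- data.frame(dataset_id = manifest$dataset_id,
                      nominal_donor = manifest$donor,
                      true_donor = manifest$donor, stringsAsFactors = FALSE)
  if (n_swaps > 0L) {
    hit_donors <- sample(donors, n_swaps)
    for (d in hit_donors) {
      ds <- sample(manifest$dataset_id[manifest$donor == d], 1L)
      truth$true_donor[truth$dataset_id == ds] <-
        sample(setdiff(donors, d), 1L)
    }
  }

  fingerprints <- list()
  for (k in seq_len(nrow(manifest))) {
    id <- manifest$dataset_id[[k]]
    ind <- individuals[[truth$true_donor[[k]]]]
    reads <- simulate_reads(ind, map, assay)
    fingerprints[[id]] <- build_fingerprint(reads, map, filters,
                                            sample_id = id)
  }
  structure(list(manifest = manifest, fingerprints = fingerprints,
                 truth = truth, individuals = individuals),
            class = "sim_cohort")
}
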