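FLAG_UNMAPPED <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_DUPLICATE <- 0x400L

ERROR_PROB_MIN <- 1e-6   # e = 0 would zero out likelihood factors
ERROR_PROB_MAX <- 0.5    # information-free bound

#' Read/base filter configuration
#'
#' Defaults follow the standard fingerprinting filters: only non-secondary,
#' non-duplicate reads with mapping quality strictly greater than 20
#' contribute, and bases must have quality of at least 20.
#'
#' @param min_mapping_quality Exclusive lower bound on MAPQ (default 20).
#' @param min_base_quality Inclusive lower bound on base quality (default 20).
#' @param exclude_secondary Drop secondary alignments (default TRUE).
#' @param exclude_duplicates Drop duplicate-flagged reads (default TRUE).
#' @return A list of class `read_filter_config`.
#' @export
read_filter_config <- function(min_mapping_quality = 20L,
                               min_base_quality = 20L,
                               exclude_secondary = TRUE,
                               exclude_duplicates = TRUE) {
  stopifnot(min_mapping_quality >= 0, min_base_quality >= 0)
  structure(list(min_mapping_quality = as.integer(min_mapping_quality),
                 min_base_quality = as.integer(min_base_quality),
                 exclude_secondary = isTRUE(exclude_secondary),
                 exclude_duplicates = isTRUE(exclude_duplicates)),
            class = "read_filter_config")
}

#' Likelihood of a single base observation given a diploid genotype
#'
#' For an anchor with major allele A and minor allele B and a base already
#' translated to the anchor's alleles, the likelihood of observing the base
#' with error probability e is: genotype AA -> (1 - e) for a MAJOR
#' observation and e for MINOR; AB -> 0.5 regardless of e; BB -> e for MAJOR
#' and (1 - e) for MINOR. The model assumes an error switches the observed
#' allele to the other allele, so MAJOR and MINOR likelihoods sum to 1 for
#' every genotype.
#'
#' @param allele `"MAJOR"` or `"MINOR"` (vectorized).
#' @param error_prob Error probability in (0, 0.5] (vectorized).
#' @param genotype `"AA"`, `"AB"` or `"BB"` (vectorized).
#' @return Probability of the observation.
#' @export
observation_likelihood <- function(allele, error_prob, genotype) {
  stopifnot(all(allele %in% c("MAJOR", "MINOR")),
            all(genotype %in% c("AA", "AB", "BB")),
            all(error_prob > 0 & error_prob <= 0.5))
  is_major <- allele == "MAJOR"
  out <- numeric(length(is_major))
  aa <- genotype == "AA"; bb <- genotype == "BB"
  out[aa] <- ifelse(is_major[aa], 1 - error_prob[aa], error_prob[aa])
  out[genotype == "AB"] <- 0.5
  out[bb] <- ifelse(is_major[bb], error_prob[bb], 1 - error_prob[bb])
  out
}

#' Aggregate a block's observations into log10 genotype likelihoods
#'
#' Observations within a block are treated as independent, so the block
#' likelihood for each genotype is the product over observations; an empty
#' observation set yields the empty product (log-likelihoods 0, 0, 0), which
#' later contributes exactly nothing to the LOD.
#'
#' @param observations Data.frame with columns `allele` (`"MAJOR"`/`"MINOR"`),
#'   `error_prob` and `source_id` (read-pair identifier; duplicates are a
#'   contract violation because evidence must be independent).
#' @return List with `ll` (named numeric: log10 likelihoods for AA, AB, BB)
#'   and `n_obs`.
#' @export
block_likelihoods <- function(observations) {
  if (is.null(observations) || nrow(observations) == 0L) {
    return(list(ll = c(AA = 0, AB = 0, BB = 0), n_obs = 0L))
  }
  if (anyDuplicated(observations$source_id)) {
    stop("duplicate source_id within a block: evidence must be one observation per read-pair")
  }
  e <- observations$error_prob
  maj <- observations$allele == "MAJOR"
  ll_aa <- sum(log10(ifelse(maj, 1 - e, e)))
  ll_ab <- nrow(observations) * log10(0.5)
  ll_bb <- sum(log10(ifelse(maj, e, 1 - e)))
  list(ll = c(AA = ll_aa, AB = ll_ab, BB = ll_bb),
       n_obs = nrow(observations))
}

#' Extract filtered allele observations from aligned reads
#'
#' Applies the read filters, looks up every map SNP overlapped by a retained
#' read, keeps bases with sufficient quality that match the site's major or
#' minor allele, and translates member-SNP bases to the block anchor's
#' alleles through the stored phase (`"+"`: member major is evidence for the
#' anchor's major allele; `"-"`: member major is evidence for the anchor's
#' minor allele). Evidence independence is enforced by using at most one
#' observation per read-pair across the whole map (the first usable site in
#' (chrom, pos) order); when both mates of a pair cover the same site, the
#' higher-quality base is used if they agree and the pair is discarded at
#' that site if they disagree.
#'
#' @param reads A read-set data.frame (see [read_sam()]) with columns
#'   `qname`, `flag`, `chrom`, `pos`, `mapq`, `cigar`, `seq`, `qual`.
#' @param map A `haplotype_map`.
#' @param filters A `read_filter_config`.
#' @return Data.frame with columns `anchor`, `allele`, `error_prob`,
#'   `source_id`.
#' @export
extract_observations <- function(reads, map, filters = read_filter_config()) {
  empty <- data.frame(anchor = character(), allele = character(),
                      error_prob = numeric(), source_id = character(),
                      stringsAsFactors = FALSE)
  if (is.null(reads) || nrow(reads) == 0L || nrow(map) == 0L) return(empty)

  keep <- bitwAnd(reads$flag, FLAG_UNMAPPED) == 0L &
    reads$mapq > filters$min_mapping_quality
  if (filters$exclude_secondary) {
    keep <- keep & bitwAnd(reads$flag, FLAG_SECONDARY) == 0L
  }
  if (filters$exclude_duplicates) {
    keep <- keep & bitwAnd(reads$flag, FLAG_DUPLICATE) == 0L
  }
  reads <- reads[keep, , drop = FALSE]
  if (!nrow(reads)) return(empty)

  read_contigs <- unique(reads$chrom)
  if (!any(read_contigs %in% unique(map$chrom)) && nrow(reads) > 0L) {
    stop("no read contig matches the map; map contigs missing from input: ",
         paste(setdiff(unique(map$chrom), read_contigs), collapse = ", "))
  }

  # map row order is (chrom, pos); site rank encodes the first-usable-site rule
  hits_list <- list()
  rlen <- nchar(reads$seq)
  simple <- grepl("^[0-9]+M$", reads$cigar)
  for (chrom in intersect(unique(map$chrom), read_contigs)) {
    srow <- which(map$chrom == chrom)
    rrow <- which(reads$chrom == chrom)
    if (!length(srow) || !length(rrow)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = map$pos[srow], width = 1L),
      IRanges::IRanges(start = reads$pos[rrow], width = rlen[rrow]))
    if (!length(ov)) next
    hits_list[[chrom]] <- data.frame(
      site = srow[S4Vectors::queryHits(ov)],
      read = rrow[S4Vectors::subjectHits(ov)])
  }
  if (!length(hits_list)) return(empty)
  hits <- do.call(rbind, hits_list)

  # base + quality at each hit; simple all-M CIGARs are vectorized, others walk
  off <- map$pos[hits$site] - reads$pos[hits$read] + 1L
  base <- rep(NA_character_, nrow(hits))
  bq <- rep(NA_integer_, nrow(hits))
  sv <- simple[hits$read]
  if (any(sv)) {
    base[sv] <- substring(reads$seq[hits$read[sv]], off[sv], off[sv])
    qch <- substring(reads$qual[hits$read[sv]], off[sv], off[sv])
    bq[sv] <- utf8ToInt(paste(qch, collapse = "")) - 33L
  }
  if (any(!sv)) {
    for (k in which(!sv)) {
      qo <- query_offset(reads$cigar[hits$read[k]], reads$pos[hits$read[k]],
                         map$pos[hits$site[k]])
      if (!is.na(qo)) {
        base[k] <- substring(reads$seq[hits$read[k]], qo, qo)
        bq[k] <- utf8ToInt(substring(reads$qual[hits$read[k]], qo, qo)) - 33L
      }
    }
  }

  ok <- !is.na(base) & bq >= filters$min_base_quality
  site_major <- map$major[hits$site]
  site_minor <- map$minor[hits$site]
  ok <- ok & (base == site_major | base == site_minor)
  hits <- hits[ok, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  base <- base[ok]; bq <- bq[ok]

  obs_major <- base == map$major[hits$site]      # observation in site alleles
  flip <- map$phase[hits$site] == "-"
  anchor_major <- xor(obs_major, flip)           # translated to anchor alleles

  qname <- reads$qname[hits$read]
  ord <- order(qname, hits$site, -bq, method = "radix")
  qn <- qname[ord]; st <- hits$site[ord]
  is_maj <- anchor_major[ord]; bqs <- bq[ord]
  n <- length(ord)

  # overlapping mates at one site: rows are grouped by (qname, site) with the
  # highest base quality first; keep that row when the mates agree, drop the
  # whole group when they disagree
  first <- c(TRUE, qn[-1] != qn[-n] | st[-1] != st[-n])
  gid <- cumsum(first)
  n_major <- rowsum(as.integer(is_maj), gid)[, 1]
  g_size <- tabulate(gid)
  discordant <- n_major > 0L & n_major < g_size
  keep <- first & !discordant[gid]

  # one observation per read-pair across the whole map: sites are in
  # ascending (chrom, pos) order within each qname, so the first survivor
  # per qname is the first usable site
  qn <- qn[keep]; st <- st[keep]; is_maj <- is_maj[keep]; bqs <- bqs[keep]
  pick <- !duplicated(qn)

  data.frame(anchor = map$anchor[st[pick]],
             allele = ifelse(is_maj[pick], "MAJOR", "MINOR"),
             error_prob = pmin(pmax(10^(-bqs[pick] / 10), ERROR_PROB_MIN),
                               ERROR_PROB_MAX),
             source_id = qn[pick], stringsAsFactors = FALSE)
}

# 1-based query offset of a reference position within a read, walking the
# CIGAR; NA when the position falls in a deletion/skip or outside the read.
query_offset <- function(cigar, read_pos, ref_pos) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  rpos <- read_pos; qpos <- 1L
  for (i in seq_along(op)) {
    consumes_ref <- op[i] %in% c("M", "D", "N", "=", "X")
    consumes_query <- op[i] %in% c("M", "I", "S", "=", "X")
    if (consumes_ref && ref_pos < rpos + len[i] && ref_pos >= rpos) {
      if (op[i] %in% c("M", "=", "X")) {
        return(qpos + (ref_pos - rpos))
      }
      return(NA_integer_)
    }
    if (consumes_ref) rpos <- rpos + len[i]
    if (consumes_query) qpos <- qpos + len[i]
  }
  NA_integer_
}

#' Build a fingerprint from aligned reads
#'
#' A fingerprint holds, for every anchor of the map, the log10 likelihoods
#' of the three diploid block genotypes (AA, AB, BB) given the filtered
#' observations, plus the observation count. Blocks with no observations are
#' retained with likelihoods (0, 0, 0) so they contribute exactly zero LOD.
#'
#' @param reads A read-set data.frame, or `NULL` for an empty fingerprint.
#' @param map A `haplotype_map`.
#' @param filters A `read_filter_config`.
#' @param sample_id Sample name recorded in the fingerprint.
#' @return An object of class `fingerprint`.
#' @export
build_fingerprint <- function(reads, map, filters = read_filter_config(),
                              sample_id = "sample") {
  obs <- extract_observations(reads, map, filters)
  fingerprint_from_observations(obs, map, sample_id)
}

#' Assemble a fingerprint from pre-extracted observations
#'
#' @param obs Observation data.frame as returned by [extract_observations()].
#' @param map A `haplotype_map`.
#' @param sample_id Sample name.
#' @return A `fingerprint`.
#' @export
fingerprint_from_observations <- function(obs, map, sample_id = "sample") {
  anchors <- map_anchors(map)
  n <- nrow(anchors)
  ll <- matrix(0, nrow = n, ncol = 3,
               dimnames = list(anchors$name, c("AA", "AB", "BB")))
  n_obs <- integer(n)
  if (nrow(obs)) {
    idx <- match(obs$anchor, anchors$name)
    if (anyNA(idx)) stop("observations reference anchors absent from the map")
    maj <- obs$allele == "MAJOR"
    l_aa <- log10(ifelse(maj, 1 - obs$error_prob, obs$error_prob))
    l_bb <- log10(ifelse(maj, obs$error_prob, 1 - obs$error_prob))
    agg <- rowsum(cbind(l_aa, l_bb, 1), idx)
    rows <- as.integer(rownames(agg))
    ll[rows, 1] <- agg[, 1]
    ll[rows, 2] <- agg[, 3] * log10(0.5)
    ll[rows, 3] <- agg[, 2]
    n_obs[rows] <- as.integer(agg[, 3])
  }
  new_fingerprint(sample_id, anchors$name, ll, n_obs, map_checksum(map))
}

new_fingerprint <- function(sample_id, anchors, ll, n_obs, checksum) {
  structure(list(sample_id = sample_id,
                 blocks = data.frame(anchor = anchors,
                                     ll_AA = ll[, 1], ll_AB = ll[, 2],
                                     ll_BB = ll[, 3], n_obs = n_obs,
                                     row.names = NULL,
                                     stringsAsFactors = FALSE),
                 map_checksum = checksum),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint '%s': %d blocks, %d with observations (total %d obs)\n",
              x$sample_id, nrow(x$blocks), sum(x$blocks$n_obs > 0L),
              sum(x$blocks$n_obs)))
  invisible(x)
}

#' Persist a fingerprint as VCF
#'
#' One VCF 4.2 record per map anchor; REF/ALT are the map's major/minor
#' alleles, FORMAT fields are GT (argmax genotype, `./.` for blocks without
#' observations) and GL (log10 likelihoods in order AA, AB, BB, stored as
#' floating point so round trips are exact to 1e-6), INFO field NOBS carries
#' the observation count. The map checksum is embedded in the header and
#' verified on reading.
#'
#' @param fp A `fingerprint`.
#' @param map The `haplotype_map` the fingerprint was extracted with.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
fingerprint_to_vcf <- function(fp, map, path) {
  stopifnot(inherits(fp, "fingerprint"))
  if (!identical(fp$map_checksum, map_checksum(map))) {
    stop("fingerprint was extracted with a different map (checksum mismatch)")
  }
  anchors <- map_anchors(map)
  b <- fp$blocks[match(anchors$name, fp$blocks$anchor), , drop = FALSE]
  gt <- c("0/0", "0/1", "1/1")[max.col(as.matrix(b[, c("ll_AA", "ll_AB", "ll_BB")]),
                                       ties.method = "first")]
  gt[b$n_obs == 0L] <- "./."
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=ldcheck",
    paste0("##ldcheck_map_checksum=", fp$map_checksum),
    "##INFO=<ID=NOBS,Number=1,Type=Integer,Description=\"Filtered allele observations in block\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Argmax block genotype\">",
    "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"Log10 genotype likelihoods (AA,AB,BB)\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", fp$sample_id),
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tNOBS=%d\tGT:GL\t%s:%s",
            anchors$chrom, anchors$pos, anchors$name, anchors$major,
            anchors$minor, b$n_obs, gt,
            paste(format_gl(b$ll_AA), format_gl(b$ll_AB), format_gl(b$ll_BB),
                  sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

format_gl <- function(x) {
  out <- sprintf("%.10g", x)
  out[!is.finite(x)] <- ifelse(x[!is.finite(x)] < 0, "-1e999", "1e999")
  out
}

#' Load a fingerprint from VCF
#'
#' Records at map anchors populate the fingerprint; anchors missing from the
#' VCF become no-observation blocks; records at non-map sites are ignored
#' (their count is reported in a message). The embedded map checksum must
#' match `map`.
#'
#' @param path VCF path written by [fingerprint_to_vcf()].
#' @param map The `haplotype_map` to bind against.
#' @return A `fingerprint`.
#' @export
vcf_to_fingerprint <- function(path, map) {
  if (!file.exists(path)) stop("fingerprint VCF does not exist: ", path)
  lines <- readLines(path)
  header <- lines[startsWith(lines, "##")]
  chk_line <- grep("^##ldcheck_map_checksum=", header, value = TRUE)
  checksum <- sub("^##ldcheck_map_checksum=", "", chk_line[1])
  want <- map_checksum(map)
  if (!length(chk_line) || !identical(checksum, want)) {
    stop("fingerprint VCF was extracted with a different map (checksum mismatch)")
  }
  col_line <- grep("^#CHROM", lines, value = TRUE)
  sample_id <- tail(strsplit(col_line[1], "\t", fixed = TRUE)[[1]], 1L)
  body <- lines[!startsWith(lines, "#")]
  anchors <- map_anchors(map)
  ll <- matrix(0, nrow = nrow(anchors), ncol = 3,
               dimnames = list(anchors$name, c("AA", "AB", "BB")))
  n_obs <- integer(nrow(anchors))
  skipped <- 0L
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    ids <- vapply(f, `[[`, "", 3L)
    idx <- match(ids, anchors$name)
    skipped <- sum(is.na(idx))
    for (k in which(!is.na(idx))) {
      rec <- f[[k]]
      nobs <- as.integer(sub("^.*NOBS=([0-9]+).*$", "\\1", rec[[8]]))
      gl <- strsplit(sub("^[^:]*:", "", rec[[10]]), ",", fixed = TRUE)[[1]]
      ll[idx[[k]], ] <- as.numeric(gl)
      n_obs[[idx[[k]]]] <- nobs
    }
  }
  if (skipped > 0L) {
    message(sprintf("ignored %d VCF record(s) at non-map sites", skipped))
  }
  new_fingerprint(sample_id, anchors$name, ll, n_obs, want)
}
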