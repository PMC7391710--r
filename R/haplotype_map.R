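#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov var ave rbinom rpois runif setNames approx
#' @importFrom utils head tail write.table read.table combn
#' @importFrom S4Vectors queryHits subjectHits

NULL

VALID_BASES <- c("A", "C", "G", "T")

#' Construct a haplotype map
#'
#' A haplotype map is an ordered collection of linkage-disequilibrium (LD)
#' blocks. Each block consists of an anchor SNP and zero or more member SNPs
#' that are in strong LD with the anchor (in the published genome-wide maps,
#' member r-squared with the anchor is at least 0.85, while anchors of
#' different blocks are approximately independent, r-squared at most 0.10).
#' All SNPs of a block share the anchor's allele frequency for the purpose of
#' genotype priors; per-member frequencies are stored for bookkeeping.
#'
#' @param snps A data.frame with columns `chrom` (character), `pos` (1-based
#'   integer position), `name` (unique SNP identifier), `major` and `minor`
#'   (single bases, distinct), `maf` (minor-allele frequency in \[0, 0.5\]),
#'   `anchor` (name of the block anchor; equal to `name` for anchor SNPs) and
#'   `phase` (`"+"` if the SNP's major allele co-occurs on haplotypes with the
#'   anchor's major allele, `"-"` if it co-occurs with the anchor's minor
#'   allele; anchors are always `"+"`).
#' @return An object of class `haplotype_map`: the validated data.frame,
#'   sorted by (chrom, pos).
#' @export
haplotype_map <- function(snps) {
  required <- c("chrom", "pos", "name", "major", "minor", "maf", "anchor", "phase")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols)) {
    stop("haplotype map is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  snps <- as.data.frame(snps)[required]
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  snps$name <- as.character(snps$name)
  snps$major <- as.character(snps$major)
  snps$minor <- as.character(snps$minor)
  snps$maf <- as.numeric(snps$maf)
  snps$anchor <- as.character(snps$anchor)
  snps$phase <- as.character(snps$phase)

  if (nrow(snps)) {
    check_map_fields(snps)
    is_anchor <- snps$name == snps$anchor
    anchors <- snps$name[is_anchor]
    if (anyDuplicated(anchors)) {
      stop("duplicate anchor SNPs: ",
           paste(unique(anchors[duplicated(anchors)]), collapse = ", "))
    }
    unknown <- !(snps$anchor %in% anchors)
    if (any(unknown)) {
      stop("member SNP(s) reference unknown anchors: ",
           paste(snps$name[unknown], collapse = ", "))
    }
    if (any(snps$phase[is_anchor] != "+")) {
      stop("anchor SNPs must have phase '+': ",
           paste(snps$name[is_anchor & snps$phase != "+"], collapse = ", "))
    }
    key <- paste(snps$chrom, snps$pos)
    if (anyDuplicated(key)) {
      stop("duplicate (chrom, pos) in map: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    }
    if (anyDuplicated(snps$name)) {
      stop("duplicate SNP names in map")
    }
    achrom <- snps$chrom[is_anchor][match(snps$anchor, anchors)]
    if (any(achrom != snps$chrom)) {
      stop("member SNP(s) on a different chromosome than their anchor: ",
           paste(snps$name[achrom != snps$chrom], collapse = ", "))
    }
    snps <- snps[order(snps$chrom, snps$pos, method = "radix"), , drop = FALSE]
  }
  rownames(snps) <- NULL
  structure(snps, class = c("haplotype_map", "data.frame"))
}

check_map_fields <- function(snps) {
  bad <- function(cond, what) {
    if (any(cond)) {
      stop(what, ": ", paste(snps$name[cond], collapse = ", "), call. = FALSE)
    }
  }
  bad(is.na(snps$pos) | snps$pos < 1L, "position must be >= 1")
  bad(!(snps$major %in% VALID_BASES), "major allele must be one of A,C,G,T")
  bad(!(snps$minor %in% VALID_BASES), "minor allele must be one of A,C,G,T")
  bad(snps$major == snps$minor, "major and minor allele must differ")
  bad(is.na(snps$maf) | snps$maf < 0 | snps$maf > 0.5,
      "MAF must lie in [0, 0.5]")
  bad(!(snps$phase %in% c("+", "-")), "phase must be '+' or '-'")
}

#' @export
print.haplotype_map <- function(x, ...) {
  sizes <- table(x$anchor)
  cat(sprintf("haplotype_map: %d SNPs in %d blocks (%d singletons, largest %d)\n",
              nrow(x), length(sizes), sum(sizes == 1L),
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' List the anchor SNPs of a map
#' @param map A `haplotype_map`.
#' @return Data.frame of anchor rows, ordered by (chrom, pos).
#' @export
map_anchors <- function(map) {
  map[map$name == map$anchor, , drop = FALSE]
}

#' Split a map into blocks
#' @param map A `haplotype_map`.
#' @return Named list (by anchor name) of data.frames, anchor row first,
#'   members following in (chrom, pos) order.
#' @export
map_blocks <- function(map) {
  rows <- split(seq_len(nrow(map)), map$anchor)
  lapply(rows, function(i) {
    blk <- map[i, , drop = FALSE]
    blk[order(blk$name != blk$anchor, blk$pos), , drop = FALSE]
  })
}

#' Checksum binding fingerprints to the map they were extracted with
#'
#' Fingerprints are only comparable when computed against the same map; the
#' checksum of the canonical serialized form is stored inside each fingerprint
#' and checked before scoring.
#'
#' @param map A `haplotype_map`.
#' @return MD5 hex digest of the canonical map file.
#' @export
map_checksum <- function(map) {
  tf <- tempfile(fileext = ".map")
  on.exit(unlink(tf))
  write_map(map, tf)
  unname(tools::md5sum(tf))
}

MAP_HEADER <- c("CHROM", "POS", "NAME", "MAJOR", "MINOR", "MAF", "ANCHOR", "PHASE")

#' Read a haplotype map file
#'
#' The map file is UTF-8, tab-delimited; comment lines start with `#`; a
#' single header line `CHROM POS NAME MAJOR MINOR MAF ANCHOR PHASE` precedes
#' one line per SNP. Lines are sorted by (CHROM, POS). Only bi-allelic SNPs
#' (single-base major and minor alleles) are accepted.
#'
#' @param path Path to a map file.
#' @return A `haplotype_map`.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("map file has no header line: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, MAP_HEADER)) {
    stop(sprintf("map file line %d: bad header (expected '%s')",
                 lineno[[1]], paste(MAP_HEADER, collapse = "\\t")))
  }
  if (length(lines) == 1L) {
    return(haplotype_map(data.frame(
      chrom = character(), pos = integer(), name = character(),
      major = character(), minor = character(), maf = numeric(),
      anchor = character(), phase = character())))
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8L)) {
    i <- which(nf != 8L)[[1]]
    stop(sprintf("map file line %d: expected 8 tab-separated fields, found %d",
                 lineno[-1][i], nf[[i]]))
  }
  m <- do.call(rbind, fields)
  pos <- suppressWarnings(as.integer(m[, 2]))
  maf <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(pos) | is.na(maf))
  if (length(bad)) {
    stop(sprintf("map file line %d: non-numeric POS or MAF", lineno[-1][bad[[1]]]))
  }
  haplotype_map(data.frame(
    chrom = m[, 1], pos = pos, name = m[, 3], major = m[, 4], minor = m[, 5],
    maf = maf, anchor = m[, 7], phase = m[, 8], stringsAsFactors = FALSE))
}

#' Write a haplotype map file
#'
#' Inverse of [read_map()]: `read_map(write_map(m))` reproduces `m`
#' field-for-field (MAF is printed with 6 decimals, so frequencies should be
#' representable at that precision). Output is sorted by (CHROM, POS).
#'
#' @param map A `haplotype_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "haplotype_map"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("# ldcheck haplotype map",
               paste(MAP_HEADER, collapse = "\t")), con)
  if (nrow(map)) {
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t%.6f\t%s\t%s",
                       map$chrom, map$pos, map$name, map$major, map$minor,
                       map$maf, map$anchor, map$phase), con)
  }
  invisible(path)
}

#' Validate a haplotype map, optionally against a phased panel
#'
#' Without a panel, checks the MAF floor. With a panel, additionally checks
#' that every member is in strong LD with its anchor (r-squared at least
#' `member_r2_min`), that anchors within `prune_window_bp` of one another are
#' approximately independent (r-squared at most `anchor_r2_max`), and that
#' each member's stored phase matches the sign of its allelic association
#' with its anchor.
#'
#' @param map A `haplotype_map`.
#' @param panel Optional `phased_panel` containing all map SNPs.
#' @param min_maf MAF floor (default 0.10).
#' @param anchor_r2_max Maximum anchor-pair r-squared inside a window
#'   (default 0.10).
#' @param member_r2_min Minimum member-to-anchor r-squared (default 0.85).
#' @param prune_window_bp Window within which anchor independence is required
#'   (default 10 kb, the pruning window).
#' @return A data.frame of violations (zero rows when the map is clean) with
#'   columns `snp`, `type`, `value`.
#' @export
validate_map <- function(map, panel = NULL, min_maf = 0.10,
                         anchor_r2_max = 0.10, member_r2_min = 0.85,
                         prune_window_bp = 10000) {
  stopifnot(inherits(map, "haplotype_map"))
  v <- list()
  add <- function(snp, type, value) {
    v[[length(v) + 1L]] <<- data.frame(snp = snp, type = type, value = value,
                                       stringsAsFactors = FALSE)
  }
  low <- map$maf < min_maf
  if (any(low)) add(map$name[low], "maf_below_min", map$maf[low])

  if (!is.null(panel)) {
    missing <- setdiff(map$name, panel$snps$name)
    if (length(missing)) {
      stop("panel is missing map SNPs: ", paste(head(missing, 5), collapse = ", "))
    }
    H <- panel$haplotypes
    col <- match(map$name, panel$snps$name)
    is_anchor <- map$name == map$anchor
    members <- which(!is_anchor)
    if (length(members)) {
      aidx <- match(map$anchor[members], map$name)
      for (k in seq_along(members)) {
        m <- members[[k]]; a <- aidx[[k]]
        r <- suppressWarnings(cor(H[, col[[m]]], H[, col[[a]]]))
        if (is.na(r)) r <- 0
        if (r * r < member_r2_min) add(map$name[[m]], "member_r2_below_min", r * r)
        want <- if (r >= 0) "+" else "-"
        if (map$phase[[m]] != want) add(map$name[[m]], "phase_mismatch", r)
      }
    }
    anc <- which(is_anchor)
    if (length(anc) > 1L) {
      ord <- order(map$chrom[anc], map$pos[anc], method = "radix")
      anc <- anc[ord]
      for (i in seq_len(length(anc) - 1L)) {
        for (j in (i + 1L):length(anc)) {
          a <- anc[[i]]; b <- anc[[j]]
          if (map$chrom[[a]] != map$chrom[[b]]) break
          if (map$pos[[b]] - map$pos[[a]] > prune_window_bp) break
          r <- suppressWarnings(cor(H[, col[[a]]], H[, col[[b]]]))
          if (is.na(r)) r <- 0
          if (r * r > anchor_r2_max) {
            add(paste(map$name[[a]], map$name[[b]], sep = "|"),
                "anchor_pair_r2_above_max", r * r)
          }
        }
      }
    }
  }
  if (!length(v)) {
    data.frame(snp = character(), type = character(), value = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
}

#' Subset a map to singleton blocks or to the largest multi-SNP blocks
#'
#' `"singletons_only"` keeps every block of size 1 (SNPs not in strong
#' linkage with any other map SNP). `"multiblocks_only"` keeps blocks of size
#' at least 2, added largest-first until the total SNP count first reaches or
#' exceeds `target_snp_count`; this is how an LD-block map of matched size is
#' produced for comparing block-based against single-SNP genotyping.
#'
#' @param map A `haplotype_map`.
#' @param mode `"singletons_only"` or `"multiblocks_only"`.
#' @param target_snp_count SNP budget for `"multiblocks_only"`; ignored for
#'   singletons.
#' @return A `haplotype_map`. If the target cannot be reached, all qualifying
#'   blocks are returned and the attribute `target_unreached` is set to TRUE.
#' @export
subset_map <- function(map, mode = c("singletons_only", "multiblocks_only"),
                       target_snp_count = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "haplotype_map"), nrow(map) > 0L)
  sizes <- table(map$anchor)
  if (mode == "singletons_only") {
    keep <- names(sizes)[sizes == 1L]
    return(haplotype_map(map[map$anchor %in% keep, , drop = FALSE]))
  }
  if (is.null(target_snp_count)) stop("multiblocks_only requires target_snp_count")
  multi <- names(sizes)[sizes >= 2L]
  if (!length(multi)) {
    out <- haplotype_map(map[0, , drop = FALSE])
    attr(out, "target_unreached") <- TRUE
    warning("map has no blocks of size >= 2")
    return(out)
  }
  # deterministic largest-first order; ties broken by anchor (chrom, pos)
  arow <- match(multi, map$name)
  ord <- order(-as.integer(sizes[multi]), map$chrom[arow], map$pos[arow],
               method = "radix")
  multi <- multi[ord]
  csum <- cumsum(as.integer(sizes[multi]))
  n_take <- which(csum >= target_snp_count)
  unreached <- !length(n_take)
  n_take <- if (unreached) length(multi) else n_take[[1]]
  out <- haplotype_map(map[map$anchor %in% multi[seq_len(n_take)], , drop = FALSE])
  if (unreached) {
    attr(out, "target_unreached") <- TRUE
    warning(sprintf("target of %d SNPs unreachable; returning all %d multi-SNP blocks",
                    target_snp_count, length(multi)))
  }
  out
}
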