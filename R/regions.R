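# Internal convention: all coordinates are 0-based, half-open [start, end),
# i.e. BED semantics. Probe and TSS positions are single 0-based bases.

#' Construct a genomic interval table
#'
#' A plain `data.frame` with columns `chrom`, `start`, `end` and optional
#' `name`, using BED coordinates (0-based, half-open). This is the container
#' used for enhancer regions, open-chromatin peaks and ChIP peaks throughout
#' the package.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start < end`, both non-negative.
#' @param name optional labels (recycled); `NA` allowed.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  }
  gi <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name), stringsAsFactors = FALSE)
  validate_intervals(gi)
  gi
}

validate_intervals <- function(gi, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(gi)))
  bad <- which(is.na(gi$chrom) | !nzchar(gi$chrom) | is.na(gi$start) |
                 is.na(gi$end) | gi$start < 0 | gi$start >= gi$end)
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: chrom='%s' start=%s end=%s",
                 what, bad[1L], gi$chrom[bad[1L]],
                 format(gi$start[bad[1L]]), format(gi$end[bad[1L]])))
  }
  invisible(gi)
}

# 0-based half-open -> GRanges (1-based closed) and back
gi2gr <- function(gi) {
  GenomicRanges::GRanges(gi$chrom,
                         IRanges::IRanges(start = gi$start + 1L, end = gi$end))
}

gr2gi <- function(gr, name = NA_character_) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             name = as.character(name), stringsAsFactors = FALSE)
}

#' Read a BED file
#'
#' Reads at least three whitespace- or tab-separated columns with BED
#' semantics (0-based, half-open). Lines starting with `track`, `browser`
#' or `#` are skipped. Malformed lines (non-integer coordinates or
#' `start >= end`) raise an error naming the offending line.
#'
#' @param path file path (plain or gzipped).
#' @return An interval `data.frame` (see [genomic_intervals()]), in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("BED line %d: fewer than 3 columns", idx[which(nf < 3L)[1L]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s_chr <- vapply(fields, `[[`, "", 2L)
  e_chr <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.numeric(s_chr))
  end <- suppressWarnings(as.numeric(e_chr))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("BED line %d: malformed coordinates '%s %s'",
                 idx[bad[1L]], s_chr[bad[1L]], e_chr[bad[1L]]))
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
  genomic_intervals(chrom, start, end, name)
}

#' Write intervals as BED
#'
#' @param gi interval `data.frame`.
#' @param path output path.
#' @export
write_bed <- function(gi, path) {
  out <- gi[, c("chrom", "start", "end")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  if ("name" %in% names(gi) && any(!is.na(gi$name))) {
    out$name <- ifelse(is.na(gi$name), ".", gi$name)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' Four-column TSV: `gene_id`, `chrom`, `tss_1based`, `strand`. Positions are
#' converted to the internal 0-based convention. Multiple TSS rows per gene
#' are allowed.
#'
#' @param path file path.
#' @return `data.frame` with `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @export
read_tss <- function(path) {
  tb <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss_1based", "strand")
  if (!all(need %in% names(tb))) {
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(tb$strand %in% c("+", "-"))) stop("TSS strand must be '+' or '-'")
  data.frame(gene_id = as.character(tb$gene_id), chrom = as.character(tb$chrom),
             tss = as.numeric(tb$tss_1based) - 1, strand = tb$strand,
             stringsAsFactors = FALSE)
}

#' Extract a TSS table from GTF `gene` lines
#'
#' The TSS is the 5' end of the gene: `start` for `+` strand genes, `end` for
#' `-` strand genes (GTF is 1-based, closed).
#'
#' @param path GTF file path.
#' @return `data.frame` with `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @export
tss_from_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9L && x[[3L]] == "gene", TRUE)
  f <- f[keep]
  if (!length(f)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      tss = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  strand <- vapply(f, `[[`, "", 7L)
  start1 <- as.numeric(vapply(f, `[[`, "", 4L))
  end1 <- as.numeric(vapply(f, `[[`, "", 5L))
  attr9 <- vapply(f, `[[`, "", 9L)
  m <- regmatches(attr9, regexpr('gene_id "[^"]+"', attr9))
  gene_id <- sub('gene_id "([^"]+)"', "\\1", m)
  tss1 <- ifelse(strand == "-", end1, start1)
  data.frame(gene_id = gene_id, chrom = vapply(f, `[[`, "", 1L),
             tss = tss1 - 1, strand = strand, stringsAsFactors = FALSE)
}

#' Read a probe manifest
#'
#' TSV with columns `probe_id`, `chrom`, `pos`. Manifests are 1-based by
#' default (as array annotation files are) and converted to the internal
#' 0-based convention.
#'
#' @param path file path.
#' @param one_based logical; is the manifest position 1-based? Default `TRUE`.
#' @return `data.frame` with `probe_id`, `chrom`, `pos` (0-based).
#' @export
read_probe_manifest <- function(path, one_based = TRUE) {
  tb <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(tb))) {
    stop("probe manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tb$probe_id)) {
    stop("duplicate probe_id in manifest: ",
         tb$probe_id[which(duplicated(tb$probe_id))[1L]])
  }
  data.frame(probe_id = as.character(tb$probe_id),
             chrom = as.character(tb$chrom),
             pos = as.numeric(tb$pos) - as.integer(one_based),
             stringsAsFactors = FALSE)
}

#' Merge (union) interval sets
#'
#' Pools any number of interval tables and merges overlapping and bookended
#' intervals, mirroring the pooling of multiple enhancer catalogs before
#' narrowing.
#'
#' @param ... interval `data.frame`s.
#' @return A merged, sorted interval `data.frame`.
#' @export
merge_intervals <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, nrow, 0L) > 0L]
  if (!length(parts)) return(genomic_intervals(character(), numeric(), numeric()))
  gi <- do.call(rbind, lapply(parts, function(p) p[, c("chrom", "start", "end")]))
  gi$name <- NA_character_
  gr <- GenomicRanges::reduce(gi2gr(gi))
  gr <- GenomicRanges::sort(gr)
  gr2gi(gr)
}

# distance from single 0-based positions to the nearest TSS base, by chrom;
# positions on chromosomes with no TSS get Inf
nearest_tss_dist <- function(chrom, pos, tss) {
  out <- rep(Inf, length(pos))
  by_chr <- split(tss$tss, tss$chrom)
  for (cc in names(by_chr)) {
    t <- sort(by_chr[[cc]])
    sel <- which(chrom == cc)
    if (!length(sel)) next
    p <- pos[sel]
    i <- findInterval(p, t)
    d_lo <- ifelse(i >= 1L, p - t[pmax(i, 1L)], Inf)
    d_hi <- ifelse(i < length(t), t[pmin(i + 1L, length(t))] - p, Inf)
    out[sel] <- pmin(d_lo, d_hi)
  }
  out
}

#' Keep only items distal to every TSS
#'
#' Filters intervals or probes to those whose distance to the nearest TSS is
#' strictly greater than `min_dist` (default 1500 bp, the conventional
#' boundary between promoter-proximal and distal regulatory space). For an
#' interval the distance is measured from its nearest base (0 if a TSS falls
#' inside); for a probe, from its single interrogated base. Items on
#' chromosomes with no TSS are kept. The filter is strand-agnostic.
#'
#' @param items interval `data.frame` (columns `chrom,start,end`) or probe
#'   `data.frame` (columns `probe_id,chrom,pos`).
#' @param tss TSS table (see [read_tss()]).
#' @param min_dist minimum distance in bases (exclusive). Default 1500.
#' @return The filtered `items`, rows in input order.
#' @export
distal_filter <- function(items, tss, min_dist = 1500) {
  stopifnot(min_dist >= 0)
  if (!nrow(items)) return(items)
  if ("pos" %in% names(items)) {
    d <- nearest_tss_dist(items$chrom, items$pos, tss)
  } else {
    validate_intervals(items)
    d_start <- nearest_tss_dist(items$chrom, items$start, tss)
    d_end <- nearest_tss_dist(items$chrom, items$end - 1, tss)
    d <- pmin(d_start, d_end)
    # a TSS strictly inside the interval means distance 0
    by_chr <- split(tss$tss, tss$chrom)
    for (cc in names(by_chr)) {
      t <- sort(by_chr[[cc]])
      sel <- which(items$chrom == cc)
      if (!length(sel)) next
      inside <- findInterval(items$end[sel] - 1, t) >
        findInterval(items$start[sel] - 1, t)
      d[sel][inside] <- 0
    }
  }
  items[d > min_dist, , drop = FALSE]
}

#' Narrow enhancers to their open-chromatin subregions
#'
#' Base-pair intersection of enhancer intervals with open-chromatin peaks
#' (DNase/FAIRE/NOMe-style peak sets). The peak set is first merged
#' (overlapping/bookended peaks unioned); each output interval is then the
#' maximal overlap of one enhancer with one merged peak. Empty
#' intersections are dropped and the result is sorted by (chrom, start).
#' The operation is idempotent: narrowing an already-narrowed set against
#' the same peaks returns it unchanged.
#'
#' @param enhancers,open_peaks interval `data.frame`s.
#' @return Sorted interval `data.frame`; `name` carries the enhancer's name.
#' @export
narrow_by_open_chromatin <- function(enhancers, open_peaks) {
  if (!nrow(enhancers) || !nrow(open_peaks)) {
    return(genomic_intervals(character(), numeric(), numeric()))
  }
  validate_intervals(enhancers, "enhancer")
  validate_intervals(open_peaks, "peak")
  ge <- gi2gr(enhancers)
  gp <- GenomicRanges::sort(GenomicRanges::reduce(gi2gr(open_peaks)))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ge, gp))
  if (!length(hits)) {
    return(genomic_intervals(character(), numeric(), numeric()))
  }
  e <- ge[S4Vectors::queryHits(hits)]
  p <- gp[S4Vectors::subjectHits(hits)]
  ov <- IRanges::pintersect(e, p)
  nm <- if ("name" %in% names(enhancers)) {
    enhancers$name[S4Vectors::queryHits(hits)]
  } else NA_character_
  out <- gr2gi(ov, name = nm)
  out <- unique(out)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map array probes into narrowed enhancer regions
#'
#' A probe is kept iff some narrowed interval contains its interrogated base
#' (`start <= pos < end`). If several intervals contain it, every membership
#' is recorded, but the probe appears once in the analysis universe
#' (`unique_probes` attribute / [probe_universe()]).
#'
#' @param probes probe `data.frame` (`probe_id`, `chrom`, `pos`; 0-based).
#' @param narrowed interval `data.frame`.
#' @return `data.frame` with one row per (probe, containing interval):
#'   `probe_id`, `chrom`, `pos`, `interval` (label `chrom:start-end`).
#' @export
map_probes <- function(probes, narrowed) {
  empty <- data.frame(probe_id = character(), chrom = character(),
                      pos = numeric(), interval = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(probes) || !nrow(narrowed)) return(empty)
  gp <- GenomicRanges::GRanges(probes$chrom,
                               IRanges::IRanges(probes$pos + 1L, width = 1L))
  gn <- gi2gr(narrowed)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gp, gn))
  if (!length(hits)) return(empty)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  data.frame(probe_id = probes$probe_id[q], chrom = probes$chrom[q],
             pos = probes$pos[q],
             interval = sprintf("%s:%d-%d", narrowed$chrom[s],
                                as.integer(narrowed$start[s]),
                                as.integer(narrowed$end[s])),
             stringsAsFactors = FALSE)
}

#' Unique probes of an enhancer-probe table
#'
#' @param mapped output of [map_probes()].
#' @return `data.frame` with one row per distinct probe.
#' @export
probe_universe <- function(mapped) {
  unique(mapped[, c("probe_id", "chrom", "pos")])
}

#' Build the enhancer-probe analysis universe
#'
#' Convenience wrapper chaining the region steps: pool and merge enhancer
#' sets, keep distal enhancers, narrow by open chromatin, distal-filter again
#' at probe level, and map probes into the narrowed regions.
#'
#' @param enhancers one interval `data.frame` or a list of them (pooled).
#' @param open_peaks open-chromatin interval `data.frame`.
#' @param tss TSS table.
#' @param probes probe manifest (`probe_id`, `chrom`, `pos`; 0-based).
#' @param min_dist distal cutoff in bases (default 1500).
#' @return List with `narrowed` (intervals), `mapped` (probe memberships) and
#'   `universe` (distinct distal enhancer probes).
#' @export
build_universe <- function(enhancers, open_peaks, tss, probes,
                           min_dist = 1500) {
  if (is.data.frame(enhancers)) enhancers <- list(enhancers)
  pooled <- do.call(merge_intervals, enhancers)
  distal_enh <- distal_filter(pooled, tss, min_dist)
  narrowed <- narrow_by_open_chromatin(distal_enh, open_peaks)
  distal_probes <- distal_filter(probes, tss, min_dist)
  mapped <- map_probes(distal_probes, narrowed)
  list(narrowed = narrowed, mapped = mapped,
       universe = probe_universe(mapped))
}
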