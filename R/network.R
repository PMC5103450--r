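#' Count linked enhancer probes per gene (TF hub ranking)
#'
#' Counts the distinct enhancer probes linked to each gene within one link
#' category. Genes whose expression tracks the activity of many enhancers
#' are candidate driver transcription factors (hubs). The table is sorted
#' by descending probe count with lexicographic gene order breaking ties.
#'
#' @param links link `data.frame` (typically the `significant` subset of
#'   [call_links()] output).
#' @param category one of `ET_Gplus`, `ET_Gminus`, `EN_Gplus`, `EN_Gminus`.
#' @param tf_list optional character vector of transcription-factor gene
#'   ids; fills the `is_tf` column.
#' @return `data.frame` with `gene_id`, `n_linked_probes`, `is_tf`.
#' @export
count_links_per_gene <- function(links, category = "ET_Gplus",
                                 tf_list = NULL) {
  valid <- c("ET_Gplus", "ET_Gminus", "EN_Gplus", "EN_Gminus")
  if (!category %in% valid) {
    stop("unknown category '", category, "'; must be one of ",
         paste(valid, collapse = ", "))
  }
  sub <- links[links$category == category, c("probe_id", "gene_id")]
  sub <- unique(sub)
  if (!nrow(sub)) {
    return(data.frame(gene_id = character(), n_linked_probes = integer(),
                      is_tf = logical(), stringsAsFactors = FALSE))
  }
  cnt <- aggregate(probe_id ~ gene_id, data = sub, FUN = length)
  names(cnt)[2L] <- "n_linked_probes"
  cnt <- cnt[order(-cnt$n_linked_probes, cnt$gene_id), , drop = FALSE]
  cnt$is_tf <- if (is.null(tf_list)) NA else cnt$gene_id %in% tf_list
  rownames(cnt) <- NULL
  cnt
}

#' Per-sample binary link states
#'
#' For each link and tumor sample, state 1 means the link's enhancer probe
#' is in its active (unmethylated) state in that sample: beta strictly
#' below `active_cut`. Missing betas give state 0.
#'
#' @param links link `data.frame` with `probe_id` and `gene_id`.
#' @param betas probes x samples beta matrix.
#' @param sheet sample sheet (`tumor` samples define the columns).
#' @param params [link_params()] (supplies `active_cut`).
#' @return Binary matrix, rows named `probe_id|gene_id`, columns tumor
#'   sample ids.
#' @export
link_state_per_sample <- function(links, betas, sheet,
                                  params = link_params()) {
  check_sheet(sheet)
  tumors <- intersect(group_ids(sheet, "tumor"), colnames(betas))
  if (!length(tumors)) stop("no tumor samples present in beta matrix")
  b <- betas[links$probe_id, tumors, drop = FALSE]
  state <- (b < params$active_cut)
  state[is.na(state)] <- FALSE
  state <- matrix(as.integer(state), nrow(state), ncol(state),
                  dimnames = list(paste(links$probe_id, links$gene_id,
                                        sep = "|"), tumors))
  state
}

#' Binary-distance Ward clustering
#'
#' Hierarchical clustering of the rows of a binary matrix using the
#' asymmetric binary distance
#' `d(x, y) = #\{exactly one of x,y is 1\} / #\{at least one is 1\}`
#' (positions where both are 0 are uninformative), with `d = 0` for a pair
#' of all-zero rows, and Ward linkage (`ward.D2`). To cluster samples pass
#' the transposed matrix. Deterministic given input order.
#'
#' @param x binary (0/1) matrix with at least one row.
#' @param k optional number of clusters to cut the dendrogram into.
#' @return List with `hclust` (the tree; `NULL` for a single row), `order`
#'   (leaf order), and `labels` (cluster labels when `k` given; for a
#'   single row, the trivial clustering).
#' @export
binary_ward_cluster <- function(x, k = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 1L)
  if (nrow(x) == 1L) {
    lab <- if (is.null(k)) NULL else setNames(1L, rownames(x))
    return(list(hclust = NULL, order = 1L, labels = lab))
  }
  d <- dist(x, method = "binary")
  d[is.na(d)] <- 0  # all-zero pairs: define distance 0
  hc <- hclust(d, method = "ward.D2")
  labels <- if (is.null(k)) NULL else cutree(hc, k = k)
  list(hclust = hc, order = hc$order, labels = labels)
}

#' Binary pairwise distance between two 0/1 vectors
#'
#' The distance used by [binary_ward_cluster()], exposed for inspection:
#' discordant positions over positions where at least one vector is 1
#' (0 if neither has any 1).
#'
#' @param x,y binary vectors of equal length.
#' @return Distance in `[0, 1]`.
#' @export
binary_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  any1 <- (x == 1) | (y == 1)
  if (!any(any1)) return(0)
  sum(xor(x == 1, y == 1)) / sum(any1)
}

#' ChIP-peak overlap enrichment between probe sets
#'
#' A probe overlaps the peak set iff any peak intersects the inclusive
#' window `[pos - window, pos + window]` around its interrogated base. For
#' every ordered pair of labeled probe sets (focal A vs background B,
#' probes of A removed from B), a 2x2 table of (in A vs in B\\A) x
#' (overlap vs not) is tested with the two-sided Fisher exact test
#' (hypergeometric tail summation); p values are Benjamini-Hochberg
#' adjusted across pairs. Degenerate margins give p = 1.
#'
#' @param probe_sets named list of probe `data.frame`s (`probe_id`,
#'   `chrom`, `pos`).
#' @param peaks interval `data.frame` of ChIP peaks.
#' @param window half-width of the window in bases (default 100,
#'   inclusive at both ends).
#' @return `data.frame` with one row per ordered set pair: `focal`,
#'   `background`, counts `a`, `b`, `c`, `d`, `odds_ratio`, `p`, `q`.
#' @export
peak_overlap_enrichment <- function(probe_sets, peaks, window = 100) {
  stopifnot(is.list(probe_sets), length(probe_sets) >= 2L,
            !is.null(names(probe_sets)))
  overlaps_peaks <- function(pr) {
    if (!nrow(pr) || !nrow(peaks)) return(setNames(rep(FALSE, nrow(pr)),
                                                   pr$probe_id))
    gw <- GenomicRanges::GRanges(
      pr$chrom, IRanges::IRanges(pmax(pr$pos - window, 0) + 1L,
                                 pr$pos + window + 1L))
    ov <- suppressWarnings(IRanges::overlapsAny(gw, gi2gr(peaks)))
    setNames(ov, pr$probe_id)
  }
  ov_by_set <- lapply(probe_sets, overlaps_peaks)
  combos <- expand.grid(focal = names(probe_sets),
                        background = names(probe_sets),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$focal != combos$background, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    fo <- combos$focal[r]; bg <- combos$background[r]
    ov_f <- ov_by_set[[fo]]
    ov_b <- ov_by_set[[bg]]
    ov_b <- ov_b[setdiff(names(ov_b), names(ov_f))]
    a <- sum(ov_f); b <- sum(!ov_f)
    c_ <- sum(ov_b); d <- sum(!ov_b)
    tab <- matrix(c(a, b, c_, d), 2L)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      p <- 1; or <- NA_real_
    } else {
      ft <- fisher.test(tab, alternative = "two.sided")
      p <- ft$p.value
      or <- unname(ft$estimate)
    }
    data.frame(focal = fo, background = bg, a = a, b = b, c = c_, d = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Histogram of same-chromosome link distances
#'
#' Bins the probe-to-TSS distances of same-chromosome links. Default bins
#' are log-spaced from 10 kb to 100 Mb (half-decade steps) with an
#' under-10 kb bin and an over-100 Mb bin; the marginal count of links
#' within 1 Mb (inclusive) is attached as `attr(, "within_1mb")`. Bin
#' counts sum to the number of same-chromosome links.
#'
#' @param links link `data.frame` annotated by [annotate_distance()].
#' @param breaks optional increasing numeric break vector (left-closed,
#'   right-open bins; last bin right-closed at `Inf`).
#' @return `data.frame` with `bin_lo`, `bin_hi`, `count`.
#' @export
distance_summary <- function(links, breaks = NULL) {
  if (is.null(breaks)) breaks <- c(0, 10^seq(4, 8, by = 0.5), Inf)
  stopifnot(all(diff(breaks) > 0))
  d <- links$distance[!is.na(links$same_chrom) & links$same_chrom]
  d <- d[!is.na(d)]
  idx <- findInterval(d, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  out <- data.frame(bin_lo = breaks[-length(breaks)],
                    bin_hi = breaks[-1L], count = counts)
  attr(out, "within_1mb") <- sum(d <= 1e6)
  out
}
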