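#' Fit an enhancer network from methylation and expression
#'
#' Runs the whole workflow on in-memory objects: builds the distal
#' open-chromatin enhancer-probe universe, classifies each probe's
#' differential methylation between tumors and normals (with the
#' contamination guard), calls enhancer-to-gene links genome-wide, and
#' summarizes the network (hub ranking, distance histogram, per-sample
#' link states).
#'
#' @param betas probes x samples beta matrix.
#' @param expr genes x samples expression matrix (normalized, log2 scale
#'   recommended).
#' @param sheet sample sheet `data.frame` (`sample_id`, `group` in
#'   tumor/normal/control).
#' @param manifest probe coordinates (`probe_id`, `chrom`, `pos`; 0-based).
#' @param enhancers enhancer interval `data.frame` or list of them
#'   (pooled and merged).
#' @param open_peaks open-chromatin interval `data.frame`.
#' @param tss TSS table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param classify_params [classify_params()].
#' @param link_params [link_params()].
#' @param min_dist distal cutoff in bases (default 1500).
#' @param tf_list optional character vector of TF gene ids for hub
#'   annotation.
#' @return Object of class `tenet`: a list with `universe`, `narrowed`,
#'   `classification`, `class_counts`, `links` (all tested pairs;
#'   `significant` column flags calls), `hubs` (ET_Gplus hub ranking),
#'   `distance_hist`, `link_states` (binary matrix over significant
#'   ET_Gplus links), the parameter objects and the `call`.
#' @seealso [call_links()], [classify_all()], [build_universe()],
#'   [simulate_cohort()]
#' @examples
#' cfg <- sim_config(n_genes = 40, n_probes = 60, n_tumor = 30,
#'                   n_normal = 10, n_control = 10, n_tf_drivers = 2,
#'                   targets_per_tf = 5, driver_penetrance = 1,
#'                   n_chrom = 1, seed = 42)
#' sim <- simulate_cohort(cfg)
#' fit <- tenet(sim$betas, sim$expr, sim$sheet, sim$genome$manifest,
#'              sim$genome$enhancers, sim$genome$open_peaks, sim$genome$tss,
#'              link_params = link_params(n_perm = 200, seed = 42))
#' fit
#' @export
tenet <- function(betas, expr, sheet, manifest, enhancers, open_peaks, tss,
                  classify_params = tenet::classify_params(),
                  link_params = tenet::link_params(), min_dist = 1500,
                  tf_list = NULL) {
  cl <- match.call()
  regions <- build_universe(enhancers, open_peaks, tss, manifest, min_dist)
  universe <- regions$universe
  keep <- intersect(universe$probe_id, rownames(betas))
  classification <- classify_all(betas[keep, , drop = FALSE], sheet,
                                 classify_params)
  links <- call_links(classification, betas, expr, sheet, link_params,
                      probes = universe, tss = tss)
  sig <- links[which(links$significant), , drop = FALSE]
  hubs <- count_links_per_gene(sig, "ET_Gplus", tf_list = tf_list)
  dist_hist <- distance_summary(sig[sig$category == "ET_Gplus", ,
                                    drop = FALSE])
  et <- sig[sig$category == "ET_Gplus", , drop = FALSE]
  states <- if (nrow(et)) {
    link_state_per_sample(et, betas, sheet, link_params)
  } else NULL
  structure(list(
    universe = universe, narrowed = regions$narrowed,
    classification = classification,
    class_counts = attr(classification, "class_counts"),
    links = links, skipped = attr(links, "skipped"),
    hubs = hubs, distance_hist = dist_hist, link_states = states,
    classify_params = classify_params, link_params = link_params,
    call = cl), class = "tenet")
}

#' @export
print.tenet <- function(x, ...) {
  cat("Enhancer network fit (tenet)\n")
  cat(sprintf("  enhancer-probe universe: %d probes in %d narrowed regions\n",
              nrow(x$universe), nrow(x$narrowed)))
  cc <- x$class_counts
  cat(sprintf(paste0("  classes: %d always_unmeth, %d always_meth, ",
                     "%d hyper, %d hypo, %d unclassified\n"),
              cc[["always_unmeth"]], cc[["always_meth"]], cc[["hyper"]],
              cc[["hypo"]], cc[["unclassified"]]))
  cat(sprintf("  tested pairs: %d (skipped: %d)\n", nrow(x$links),
              x$skipped$pairs_skipped))
  cat(sprintf("  significant links: %d at FDR %.3g (%s)\n",
              sum(x$links$significant), x$link_params$alpha,
              x$link_params$method))
  if (nrow(x$hubs)) {
    cat("  top hub genes (ET_Gplus):",
        paste(utils::head(x$hubs$gene_id, 5L), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.tenet <- function(object, ...) {
  sig <- object$links[which(object$links$significant), , drop = FALSE]
  cat_tab <- table(factor(sig$category,
                          levels = c("ET_Gplus", "ET_Gminus",
                                     "EN_Gplus", "EN_Gminus")))
  out <- list(class_counts = object$class_counts,
              n_tested = nrow(object$links),
              n_significant = nrow(sig),
              category_counts = cat_tab,
              within_1mb = attr(object$distance_hist, "within_1mb"),
              top_hubs = utils::head(object$hubs, 10L),
              skipped = object$skipped)
  class(out) <- "summary.tenet"
  out
}

#' @export
print.summary.tenet <- function(x, ...) {
  cat("Probe classification:\n")
  print(x$class_counts)
  cat(sprintf("\nLinks: %d significant of %d tested pairs\n",
              x$n_significant, x$n_tested))
  print(x$category_counts)
  cat(sprintf("Same-chromosome ET:G+ links within 1 Mb: %d\n",
              x$within_1mb %||% 0L))
  if (nrow(x$top_hubs)) {
    cat("\nTop hub genes (distinct linked enhancer probes, ET_Gplus):\n")
    print(x$top_hubs)
  }
  invisible(x)
}

#' Plot an enhancer network fit
#'
#' `type = "distance"` draws the histogram of same-chromosome ET:G+
#' probe-to-TSS distances (log-spaced bins); `type = "hubs"` a barplot of
#' the top genes by number of linked enhancer probes.
#'
#' @param x a `tenet` object.
#' @param type `"distance"` or `"hubs"`.
#' @param n_top number of genes shown for `type = "hubs"`.
#' @param ... passed to the underlying graphics call.
#' @export
plot.tenet <- function(x, type = c("distance", "hubs"), n_top = 10, ...) {
  type <- match.arg(type)
  if (type == "distance") {
    h <- x$distance_hist
    lab <- ifelse(is.finite(h$bin_hi),
                  sprintf("<%s", format(h$bin_hi, big.mark = ",",
                                        scientific = FALSE, trim = TRUE)),
                  "larger")
    graphics::barplot(h$count, names.arg = lab, las = 2,
                      ylab = "ET:G+ links (same chromosome)",
                      xlab = "probe-to-TSS distance (bp)", ...)
  } else {
    hh <- utils::head(x$hubs, n_top)
    graphics::barplot(rev(hh$n_linked_probes), names.arg = rev(hh$gene_id),
                      horiz = TRUE, las = 1,
                      xlab = "linked enhancer probes (ET_Gplus)", ...)
  }
  invisible(x)
}
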