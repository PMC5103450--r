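#' Classification parameters
#'
#' Beta-value thresholds for the four-group classification of enhancer
#' probes. A group mean below `unmeth_cut` counts as "unmethylated", above
#' `meth_cut` as "methylated"; 0.3/0.7 are the conventional beta cutpoints
#' for clearly unmethylated / methylated CpGs. `min_nonmissing` vetoes calls
#' resting on too few observed samples; it is clamped to each group's size,
#' so small cohorts (or an absent control group) are not vetoed outright.
#'
#' @param unmeth_cut beta threshold below which a group mean is
#'   "unmethylated" (default 0.3).
#' @param meth_cut beta threshold above which a group mean is "methylated"
#'   (default 0.7).
#' @param min_nonmissing minimum non-missing samples per group (default 5,
#'   clamped to group size).
#' @return Object of class `classify_params`.
#' @export
classify_params <- function(unmeth_cut = 0.3, meth_cut = 0.7,
                            min_nonmissing = 5) {
  stopifnot(unmeth_cut >= 0, meth_cut <= 1, unmeth_cut < meth_cut,
            min_nonmissing >= 0)
  structure(list(unmeth_cut = unmeth_cut, meth_cut = meth_cut,
                 min_nonmissing = min_nonmissing),
            class = "classify_params")
}

probe_classes <- c("always_unmeth", "always_meth", "hyper", "hypo",
                   "unclassified")

check_sheet <- function(sheet) {
  need <- c("sample_id", "group")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(sheet$group %in% c("tumor", "normal", "control"))) {
    stop("sample groups must be one of tumor/normal/control")
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sheet: ",
         sheet$sample_id[which(duplicated(sheet$sample_id))[1L]])
  }
  if (!any(sheet$group == "tumor") || !any(sheet$group == "normal")) {
    stop("sample sheet needs at least one tumor and one normal sample")
  }
  invisible(sheet)
}

group_ids <- function(sheet, group) sheet$sample_id[sheet$group == group]

#' Per-probe group means of beta values
#'
#' Means over non-missing beta values within the tumor, normal and control
#' groups, with counts of non-missing samples.
#'
#' @param betas probes x samples numeric matrix of beta values in `[0,1]`
#'   (`NA` permitted), with row and column names.
#' @param sheet sample sheet `data.frame` (`sample_id`, `group`).
#' @return `data.frame` with `probe_id`, `mean_tumor`, `mean_normal`,
#'   `mean_control`, `n_tumor`, `n_normal`, `n_control`.
#' @export
group_means <- function(betas, sheet) {
  check_sheet(sheet)
  missing_ids <- setdiff(sheet$sample_id, colnames(betas))
  if (length(missing_ids)) {
    stop("sample ids not in beta matrix: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  }
  one_group <- function(ids) {
    if (!length(ids)) {
      return(list(mean = rep(NA_real_, nrow(betas)),
                  n = rep(0L, nrow(betas))))
    }
    sub <- betas[, ids, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    m[n == 0L] <- NA_real_
    list(mean = m, n = n)
  }
  tu <- one_group(group_ids(sheet, "tumor"))
  no <- one_group(group_ids(sheet, "normal"))
  co <- one_group(group_ids(sheet, "control"))
  data.frame(probe_id = rownames(betas),
             mean_tumor = tu$mean, mean_normal = no$mean,
             mean_control = co$mean,
             n_tumor = tu$n, n_normal = no$n, n_control = co$n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify probes from group means
#'
#' Decision rule over the three group means (vectorized):
#' \itemize{
#'   \item `always_unmeth`: tumor and normal means both `< unmeth_cut`;
#'   \item `always_meth`: tumor and normal means both `> meth_cut`;
#'   \item `hyper` (normal-specific enhancer lost in tumors): normal mean
#'     `< unmeth_cut` and tumor mean `> meth_cut`, vetoed if the control
#'     (contamination-profile) mean is also high (`> meth_cut`);
#'   \item `hypo` (tumor-specific enhancer gained in tumors): normal mean
#'     `> meth_cut` and tumor mean `< unmeth_cut`, vetoed if the control
#'     mean is also low (`< unmeth_cut`);
#'   \item `unclassified` otherwise, including any probe whose tumor,
#'     normal, or (when a control group exists) control count of
#'     non-missing samples falls below `min_nonmissing` (clamped to the
#'     group size).
#' }
#' The control veto is a pure disqualifier: with no control samples the rule
#' reduces to the same classification without the guard.
#'
#' @param means output of [group_means()].
#' @param params [classify_params()].
#' @param group_sizes optional named vector (`tumor`, `normal`, `control`)
#'   used to clamp `min_nonmissing`; defaults to the max observed counts.
#' @return Factor of classes, one per row of `means`.
#' @export
classify_probes <- function(means, params = classify_params(),
                            group_sizes = NULL) {
  u <- params$unmeth_cut
  m <- params$meth_cut
  if (is.null(group_sizes)) {
    group_sizes <- c(tumor = max(means$n_tumor, 0),
                     normal = max(means$n_normal, 0),
                     control = max(means$n_control, 0))
  }
  min_t <- min(params$min_nonmissing, group_sizes[["tumor"]])
  min_n <- min(params$min_nonmissing, group_sizes[["normal"]])
  min_c <- min(params$min_nonmissing, group_sizes[["control"]])
  has_control <- group_sizes[["control"]] > 0

  mt <- means$mean_tumor
  mn <- means$mean_normal
  mc <- means$mean_control
  ok <- !is.na(mt) & !is.na(mn) &
    means$n_tumor >= min_t & means$n_normal >= min_n &
    (!has_control | means$n_control >= min_c)

  cls <- rep("unclassified", nrow(means))
  guard_hyper <- !is.na(mc) & mc > m   # contamination already methylated
  guard_hypo <- !is.na(mc) & mc < u    # contamination already unmethylated
  cls[ok & mt < u & mn < u] <- "always_unmeth"
  cls[ok & mt > m & mn > m] <- "always_meth"
  cls[ok & mn < u & mt > m & !guard_hyper] <- "hyper"
  cls[ok & mn > m & mt < u & !guard_hypo] <- "hypo"
  factor(cls, levels = probe_classes)
}

#' Classify all enhancer probes
#'
#' Runs [group_means()] and [classify_probes()] over a beta matrix
#' restricted to the enhancer-probe universe and returns the per-probe
#' classification with per-class counts.
#'
#' @inheritParams group_means
#' @param params [classify_params()].
#' @return `data.frame` with the group means, counts, and a `class` column;
#'   per-class totals in `attr(, "class_counts")`.
#' @export
classify_all <- function(betas, sheet, params = classify_params()) {
  if (nrow(betas) == 0L) {
    out <- data.frame(probe_id = character(), mean_tumor = numeric(),
                      mean_normal = numeric(), mean_control = numeric(),
                      n_tumor = integer(), n_normal = integer(),
                      n_control = integer(),
                      class = factor(character(), levels = probe_classes),
                      stringsAsFactors = FALSE)
    attr(out, "class_counts") <- table(out$class)
    return(out)
  }
  rng <- range(betas, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("beta values must lie in [0,1]")
  means <- group_means(betas, sheet)
  sizes <- c(tumor = sum(sheet$group == "tumor"),
             normal = sum(sheet$group == "normal"),
             control = sum(sheet$group == "control"))
  means$class <- classify_probes(means, params, group_sizes = sizes)
  attr(means, "class_counts") <- table(means$class)
  means
}
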