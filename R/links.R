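#' Link-calling parameters
#'
#' Thresholds and settings for the enhancer-to-gene association step.
#' Per-sample enhancer state is dichotomized on beta: `active`
#' (unmethylated, open) below `active_cut`, `inactive` (methylated, closed)
#' above `inactive_cut`; intermediate samples are excluded. Both
#' inequalities are strict. The defaults reuse the canonical 0.3/0.7 beta
#' cutpoints. `n_perm` controls the resolution of the permutation p value:
#' the smallest attainable p is `1/(n_perm + 1)`, so genome-wide runs with
#' many tested pairs need `n_perm` large enough that `1/(n_perm + 1)` falls
#' below the Benjamini-Hochberg threshold `alpha * k / m` for the expected
#' number of discoveries `k` out of `m` tests.
#'
#' @param active_cut beta below which a tumor sample counts as enhancer
#'   active (default 0.3).
#' @param inactive_cut beta above which it counts as inactive (default 0.7).
#' @param min_group minimum samples per side (default 5).
#' @param n_perm permutations for the empirical p value (default 1000,
#'   minimum 100).
#' @param seed integer seed; all link-stage randomness derives from it.
#' @param alpha Benjamini-Hochberg FDR level (default 0.05).
#' @param method which statistics must pass BH at `alpha` for a link to be
#'   significant: `"both"` (empirical and Wilcoxon; default), `"emp"`,
#'   or `"wilcoxon"`.
#' @return Object of class `link_params`.
#' @export
link_params <- function(active_cut = 0.3, inactive_cut = 0.7, min_group = 5,
                        n_perm = 1000, seed = 1, alpha = 0.05,
                        method = c("both", "emp", "wilcoxon")) {
  stopifnot(active_cut < inactive_cut, n_perm >= 100, min_group >= 1,
            alpha > 0, alpha < 1)
  structure(list(active_cut = active_cut, inactive_cut = inactive_cut,
                 min_group = min_group, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), alpha = alpha,
                 method = match.arg(method)),
            class = "link_params")
}

#' Split tumor samples by enhancer state at one probe
#'
#' @param probe_betas named numeric vector of the probe's beta values over
#'   tumor samples (`NA` excluded from both sides).
#' @param params [link_params()].
#' @return List with character vectors `active` (beta `< active_cut`) and
#'   `inactive` (beta `> inactive_cut`); either may be empty.
#' @export
define_groups <- function(probe_betas, params = link_params()) {
  b <- probe_betas[!is.na(probe_betas)]
  list(active = names(b)[b < params$active_cut],
       inactive = names(b)[b > params$inactive_cut])
}

#' Welch z statistic
#'
#' `z = (mean_a - mean_i) / sqrt(s_a^2/n_a + s_i^2/n_i)` with `n - 1`
#' denominator sample variances (a single observation contributes variance
#' 0). Zero variance on both sides gives `z = 0` for equal means and a
#' `+/-Inf` sentinel for unequal means.
#'
#' @param a,i numeric vectors (active and inactive side values).
#' @return The z statistic (possibly `+/-Inf`).
#' @export
welch_z <- function(a, i) {
  a <- a[!is.na(a)]; i <- i[!is.na(i)]
  n_a <- length(a); n_i <- length(i)
  stopifnot(n_a >= 1, n_i >= 1)
  v_a <- if (n_a > 1L) var(a) else 0
  v_i <- if (n_i > 1L) var(i) else 0
  se <- sqrt(v_a / n_a + v_i / n_i)
  d <- mean(a) - mean(i)
  if (se == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else {
    d / se
  }
}

# Vectorized Welch z for E (genes x n) against permutation indicator
# matrix P (n x k, 0/1 columns of common active-size n_a). Degenerate
# columns (zero variance both sides) give 0 for equal means, +/-Inf else.
welch_z_matrix <- function(E, P, n_a) {
  n <- ncol(E)
  n_i <- n - n_a
  S_tot <- rowSums(E)
  Q_tot <- rowSums(E * E)
  SA <- E %*% P
  QA <- (E * E) %*% P
  SI <- S_tot - SA
  QI <- Q_tot - QA
  m_a <- SA / n_a
  m_i <- SI / n_i
  v_a <- pmax(QA - SA * m_a, 0) / max(n_a - 1L, 1L)
  v_i <- pmax(QI - SI * m_i, 0) / max(n_i - 1L, 1L)
  if (n_a == 1L) v_a[] <- 0
  if (n_i == 1L) v_i[] <- 0
  se <- sqrt(v_a / n_a + v_i / n_i)
  d <- m_a - m_i
  z <- d / se
  deg <- se == 0
  if (any(deg)) z[deg] <- ifelse(d[deg] == 0, 0, sign(d[deg]) * Inf)
  z
}

# random permutation indicator matrix: n x n_perm, each column a uniform
# random subset of size n_a
perm_indicator <- function(n, n_a, n_perm) {
  P <- matrix(0, n, n_perm)
  for (j in seq_len(n_perm)) P[sample.int(n, n_a), j] <- 1
  P
}

#' Permutation empirical p value for the Welch z
#'
#' Group labels are permuted `n_perm` times preserving group sizes; the p
#' value uses the add-one rule
#' `p = (1 + #\{|z_perm| >= |z_obs|\}) / (1 + n_perm)`. Degenerate
#' permutations (zero variance on both sides) are counted as `|z_perm| = 0`.
#'
#' @param z_obs observed z statistic.
#' @param values numeric vector of all samples' expression values.
#' @param active logical vector (same length) marking the active side.
#' @param n_perm number of permutations.
#' @param seed integer seed (reproducible).
#' @return Empirical p value in `(0, 1]`.
#' @export
empirical_p <- function(z_obs, values, active, n_perm = 1000, seed = 1) {
  stopifnot(length(values) == length(active), n_perm >= 1)
  keep <- !is.na(values)
  values <- values[keep]; active <- active[keep]
  n <- length(values); n_a <- sum(active)
  stopifnot(n_a >= 1, n - n_a >= 1)
  set.seed(seed)
  P <- perm_indicator(n, n_a, n_perm)
  zp <- welch_z_matrix(matrix(values, 1L), P, n_a)
  zp[!is.finite(zp)] <- 0
  tol <- 1e-8 * (1 + abs(z_obs))
  if (!is.finite(z_obs)) {
    hits <- 0L  # only other degenerate (counted 0) could tie; they never reach Inf
  } else {
    hits <- sum(abs(zp) >= abs(z_obs) - tol)
  }
  (1 + hits) / (1 + n_perm)
}

#' Two-sided Wilcoxon rank-sum p value
#'
#' Exact null enumeration when the two sides together have at most 12
#' observations and no ties; otherwise the normal approximation with tie and
#' continuity correction. Identical multisets give p = 1.
#'
#' @param a,i numeric vectors (active and inactive side values).
#' @return Two-sided p value.
#' @export
wilcoxon_p <- function(a, i) {
  a <- a[!is.na(a)]; i <- i[!is.na(i)]
  stopifnot(length(a) >= 1, length(i) >= 1)
  ties <- anyDuplicated(c(a, i)) > 0L
  ex <- (length(a) + length(i)) <= 12L && !ties
  if (!ex && !ties && sd(c(a, i)) == 0) return(1)
  p <- suppressWarnings(
    stats::wilcox.test(a, i, exact = ex, correct = TRUE)$p.value)
  if (is.na(p)) 1 else min(p, 1)
}

# Vectorized normal-approximation rank-sum p for E (genes x n), active
# logical; replicates wilcox.test(exact = FALSE, correct = TRUE) two-sided.
wilcoxon_p_matrix <- function(E, active) {
  n <- ncol(E)
  n_a <- sum(active)
  n_i <- n - n_a
  R <- t(apply(E, 1L, rank))
  U <- rowSums(R[, active, drop = FALSE]) - n_a * (n_a + 1) / 2
  tiesum <- numeric(nrow(R))
  tied <- which(apply(E, 1L, anyDuplicated) > 0L)
  for (g in tied) {
    t <- rle(sort.int(R[g, ]))$lengths
    tiesum[g] <- sum(t^3 - t)
  }
  sigma <- sqrt((n_a * n_i / 12) * ((n + 1) - tiesum / (n * (n - 1))))
  z <- U - n_a * n_i / 2
  z <- (z - sign(z) * 0.5) / sigma
  p <- 2 * pnorm(-abs(z))
  p[sigma == 0] <- 1
  pmin(p, 1)
}

probe_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483647)
}

#' Call enhancer-to-gene links genome-wide
#'
#' For every differentially methylated probe (class `hypo` or `hyper`) and
#' every gene, tumors are split into enhancer-active and enhancer-inactive
#' groups on the probe's beta values and three statistics are computed for
#' the gene's expression: the Welch z, a label-permutation empirical p, and
#' the two-sided Wilcoxon rank-sum p. Benjamini-Hochberg adjustment is
#' applied globally across all tested pairs (separately for the empirical
#' and Wilcoxon p values); a link is `significant` according to
#' `params$method`. Direction is the sign of z (`+` means expression is
#' higher when the enhancer is active) and the category pairs the probe
#' class with the direction: `hypo` probes give tumor-specific enhancer
#' links `ET_Gplus`/`ET_Gminus`, `hyper` probes normal-specific
#' `EN_Gplus`/`EN_Gminus`. Pairs with fewer than `min_group` samples on
#' either side are skipped and counted; genes with all-zero expression are
#' dropped before testing.
#'
#' @param classes classification `data.frame` from [classify_all()] (or any
#'   `data.frame` with `probe_id` and `class`).
#' @param betas probes x samples beta matrix.
#' @param expr genes x samples expression matrix (normalized, e.g. log2).
#' @param sheet sample sheet `data.frame`.
#' @param params [link_params()].
#' @param probes optional probe coordinate `data.frame` (`probe_id`,
#'   `chrom`, `pos`); when given, probe coordinates are attached.
#' @param tss optional TSS table; when given, links are annotated with
#'   [annotate_distance()].
#' @return `data.frame` of all tested pairs with columns `probe_id`,
#'   `gene_id`, `probe_class`, `n_active`, `n_inactive`, `z`, `p_emp`,
#'   `p_wilcoxon`, `q`, `q_wilcoxon`, `direction`, `category`,
#'   `degenerate`, `significant` (plus distance columns when `tss` is
#'   given). Skip counts are in `attr(, "skipped")`.
#' @export
call_links <- function(classes, betas, expr, sheet, params = link_params(),
                       probes = NULL, tss = NULL) {
  check_sheet(sheet)
  tumors <- group_ids(sheet, "tumor")
  miss_b <- setdiff(tumors, colnames(betas))
  miss_e <- setdiff(tumors, colnames(expr))
  if (length(miss_b) || length(miss_e)) {
    stop("tumor samples missing from matrices: ",
         paste(utils::head(unique(c(miss_b, miss_e)), 5L), collapse = ", "))
  }
  cls <- as.character(classes$class)
  diff_probes <- classes$probe_id[cls %in% c("hypo", "hyper")]
  diff_probes <- intersect(diff_probes, rownames(betas))
  class_of <- setNames(cls, classes$probe_id)

  ex <- expr[, tumors, drop = FALSE]
  nonzero <- rowSums(ex != 0, na.rm = TRUE) > 0
  n_dropped_genes <- sum(!nonzero)
  ex <- ex[nonzero, , drop = FALSE]
  genes <- rownames(ex)

  empty <- data.frame(probe_id = character(), gene_id = character(),
                      probe_class = character(), n_active = integer(),
                      n_inactive = integer(), z = numeric(),
                      p_emp = numeric(), p_wilcoxon = numeric(),
                      q = numeric(), q_wilcoxon = numeric(),
                      direction = character(), category = character(),
                      degenerate = logical(), significant = logical(),
                      stringsAsFactors = FALSE)
  skipped <- list(probes_skipped = 0L, pairs_skipped = 0L,
                  genes_dropped = n_dropped_genes)
  if (!length(diff_probes) || !length(genes)) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }

  res <- vector("list", length(diff_probes))
  for (k in seq_along(diff_probes)) {
    pid <- diff_probes[k]
    grp <- define_groups(betas[pid, tumors], params)
    n_a <- length(grp$active); n_i <- length(grp$inactive)
    if (n_a < params$min_group || n_i < params$min_group) {
      skipped$probes_skipped <- skipped$probes_skipped + 1L
      skipped$pairs_skipped <- skipped$pairs_skipped + length(genes)
      next
    }
    samples <- c(grp$active, grp$inactive)
    act <- c(rep(TRUE, n_a), rep(FALSE, n_i))
    E <- ex[, samples, drop = FALSE]
    complete <- rowSums(is.na(E)) == 0L
    n <- length(samples)

    z <- rep(NA_real_, length(genes))
    p_emp <- rep(NA_real_, length(genes))
    p_w <- rep(NA_real_, length(genes))
    pair_skip <- rep(FALSE, length(genes))

    if (any(complete)) {
      Ec <- E[complete, , drop = FALSE]
      z_obs <- drop(welch_z_matrix(Ec, matrix(as.numeric(act)), n_a))
      set.seed(probe_seed(params$seed, k))
      P <- perm_indicator(n, n_a, params$n_perm)
      Zp <- welch_z_matrix(Ec, P, n_a)
      Zp[!is.finite(Zp)] <- 0
      tol <- 1e-8 * (1 + abs(z_obs))
      fin <- is.finite(z_obs)
      hits <- integer(sum(complete))
      if (any(fin)) {
        hits[fin] <- rowSums(abs(Zp[fin, , drop = FALSE]) >=
                               abs(z_obs[fin]) - tol[fin])
      }
      z[complete] <- z_obs
      p_emp[complete] <- (1 + hits) / (1 + params$n_perm)
      if (n > 12L) {
        p_w[complete] <- wilcoxon_p_matrix(Ec, act)
      } else {
        p_w[complete] <- vapply(seq_len(nrow(Ec)), function(g)
          wilcoxon_p(Ec[g, act], Ec[g, !act]), 0)
      }
    }
    if (any(!complete)) {
      for (g in which(!complete)) {
        vals <- E[g, ]
        ok <- !is.na(vals)
        if (sum(ok & act) < params$min_group ||
            sum(ok & !act) < params$min_group) {
          pair_skip[g] <- TRUE
          next
        }
        zg <- welch_z(vals[ok & act], vals[ok & !act])
        z[g] <- zg
        p_emp[g] <- empirical_p(zg, vals[ok], act[ok], params$n_perm,
                                probe_seed(params$seed, k) + g)
        p_w[g] <- wilcoxon_p(vals[ok & act], vals[ok & !act])
      }
    }
    keep <- !pair_skip & !is.na(z)
    skipped$pairs_skipped <- skipped$pairs_skipped + sum(!keep)
    if (!any(keep)) next
    res[[k]] <- data.frame(
      probe_id = pid, gene_id = genes[keep],
      probe_class = class_of[[pid]],
      n_active = n_a, n_inactive = n_i,
      z = z[keep], p_emp = p_emp[keep], p_wilcoxon = p_w[keep],
      degenerate = !is.finite(z[keep]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  links <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(links)) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  links$q <- p.adjust(links$p_emp, method = "BH")
  links$q_wilcoxon <- p.adjust(links$p_wilcoxon, method = "BH")
  links$direction <- ifelse(links$z > 0, "+", "-")
  links$category <- paste0(ifelse(links$probe_class == "hypo", "ET", "EN"),
                           ifelse(links$direction == "+", "_Gplus",
                                  "_Gminus"))
  links$significant <- switch(params$method,
    both = links$q <= params$alpha & links$q_wilcoxon <= params$alpha,
    emp = links$q <= params$alpha,
    wilcoxon = links$q_wilcoxon <= params$alpha)
  if (!is.null(probes)) {
    idx <- match(links$probe_id, probes$probe_id)
    links$probe_chrom <- probes$chrom[idx]
    links$probe_pos <- probes$pos[idx]
  }
  if (!is.null(tss)) {
    if (is.null(probes)) stop("annotating distance requires probe coordinates")
    links <- annotate_distance(links, tss)
  }
  rownames(links) <- NULL
  attr(links, "skipped") <- skipped
  attr(links, "params") <- params
  links
}

#' Annotate links with probe-to-TSS distance
#'
#' For each link, `distance` is the minimum over the gene's TSSs on the
#' probe's chromosome of `|probe_pos - tss|`; `same_chrom` records whether
#' the gene has any TSS on the probe's chromosome, and `within_1mb` is true
#' for same-chromosome links with `distance <= 1e6` (inclusive). Links whose
#' gene is missing from the TSS table are kept with `NA` distance and a
#' warning.
#'
#' @param links link `data.frame` with `probe_chrom` and `probe_pos` columns
#'   (as produced by [call_links()] with `probes` supplied).
#' @param tss TSS table.
#' @return `links` with `same_chrom`, `distance`, `within_1mb` columns.
#' @export
annotate_distance <- function(links, tss) {
  if (!all(c("probe_chrom", "probe_pos") %in% names(links))) {
    stop("links lack probe coordinates (probe_chrom/probe_pos)")
  }
  links$same_chrom <- NA
  links$distance <- NA_real_
  if (nrow(links) == 0L) {
    links$within_1mb <- logical(0)
    return(links)
  }
  missing_genes <- setdiff(unique(links$gene_id), unique(tss$gene_id))
  if (length(missing_genes)) {
    warning("genes missing from TSS table: ",
            paste(utils::head(missing_genes, 5L), collapse = ", "))
  }
  key <- paste(links$gene_id, links$probe_chrom, sep = "\r")
  tss_key <- paste(tss$gene_id, tss$chrom, sep = "\r")
  tss_by_key <- split(tss$tss, tss_key)
  gene_chroms <- split(tss$chrom, tss$gene_id)
  has_gene <- links$gene_id %in% names(gene_chroms)
  links$same_chrom[has_gene] <- key[has_gene] %in% names(tss_by_key)
  on_chrom <- which(!is.na(links$same_chrom) & links$same_chrom)
  if (length(on_chrom)) {
    links$distance[on_chrom] <- vapply(on_chrom, function(r)
      min(abs(links$probe_pos[r] - tss_by_key[[key[r]]])), 0)
  }
  links$within_1mb <- !is.na(links$same_chrom) & links$same_chrom &
    !is.na(links$distance) & links$distance <= 1e6
  links
}
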