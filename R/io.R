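#' Read a beta or expression matrix
#'
#' TSV with a header row of sample ids and the first column holding row ids
#' (probes or genes). `NA` and empty cells are missing. Beta matrices are
#' validated to lie in `[0,1]`, with the offending probe named on error.
#' Gzipped files are read transparently.
#'
#' @param path file path.
#' @param kind `"beta"` or `"expression"`.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path, kind = c("beta", "expression")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  tb <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("NA", ""))
  if (ncol(tb) < 2L) stop("matrix file needs an id column plus samples")
  ids <- as.character(tb[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate row id in ", path, ": ", ids[which(duplicated(ids))[1L]])
  }
  m <- as.matrix(tb[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (kind == "beta") {
    bad <- which(rowSums(m < 0 | m > 1, na.rm = TRUE) > 0)
    if (length(bad)) {
      stop("beta value out of [0,1] for probe ", ids[bad[1L]])
    }
  }
  m
}

#' Write a matrix as TSV
#'
#' Inverse of [read_matrix()]: first column `id_col` with row names, then
#' one column per sample.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name of the id column (default `"id"`).
#' @export
write_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id` and `group` (`tumor`, `normal`, `control`);
#' additional columns (e.g. a subtype label) are carried through.
#'
#' @param path file path.
#' @return Validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  check_sheet(sheet)
  sheet
}

#' Read a run configuration file
#'
#' Plain `key = value` lines (`#` comments allowed). Known numeric keys are
#' parsed as numbers; unknown keys are rejected so typos fail loudly.
#' Recognized keys: the fields of [classify_params()] and [link_params()],
#' `min_dist`, and the input/output paths `enhancers` (comma-separated
#' list), `open_peaks`, `tss`, `manifest`, `betas`, `expr`, `sheet`,
#' `tf_list`, `out_dir`.
#'
#' @param path file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.*)$",
                                  lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("cannot parse config line: '", lines[bad[1L]], "'")
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  numeric_keys <- c("unmeth_cut", "meth_cut", "min_nonmissing",
                    "active_cut", "inactive_cut", "min_group", "n_perm",
                    "seed", "alpha", "min_dist")
  path_keys <- c("enhancers", "open_peaks", "tss", "manifest", "betas",
                 "expr", "sheet", "tf_list", "out_dir", "method")
  unknown <- setdiff(keys, c(numeric_keys, path_keys))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicate config key: ",
                                keys[which(duplicated(keys))[1L]])
  out <- as.list(vals)
  names(out) <- keys
  for (k in intersect(keys, numeric_keys)) {
    v <- suppressWarnings(as.numeric(out[[k]]))
    if (is.na(v)) stop("config key '", k, "' must be numeric")
    out[[k]] <- v
  }
  if ("enhancers" %in% keys) {
    out$enhancers <- trimws(strsplit(out$enhancers, ",")[[1L]])
  }
  out
}

pick <- function(cfg, keys, ctor) {
  args <- cfg[intersect(names(cfg), keys)]
  do.call(ctor, args)
}

#' Run the full pipeline from files
#'
#' Executes the stages in order (regions, classify, links, summarize) from
#' a configuration (a [read_run_config()] path or an equivalent list),
#' writing TSV outputs and a machine-readable JSON run manifest (config
#' hash, seed, per-stage row counts) to `out_dir`. Any stage error aborts
#' with the stage name. Reruns with the same config and seed produce
#' identical outputs.
#'
#' @param config path to a config file or a named list.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return Invisibly, the fitted [tenet()] object.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("run_pipeline needs an out_dir")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inputs <- stage("input", {
    need <- c("enhancers", "open_peaks", "tss", "manifest", "betas",
              "expr", "sheet")
    miss <- setdiff(need, names(config))
    if (length(miss)) stop("missing config keys: ",
                           paste(miss, collapse = ", "))
    for (p in c(config$enhancers, config$open_peaks, config$tss,
                config$manifest, config$betas, config$expr, config$sheet)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
    list(enhancers = lapply(config$enhancers, read_bed),
         open_peaks = read_bed(config$open_peaks),
         tss = read_tss(config$tss),
         manifest = read_probe_manifest(config$manifest),
         betas = read_matrix(config$betas, "beta"),
         expr = read_matrix(config$expr, "expression"),
         sheet = read_sample_sheet(config$sheet),
         tf_list = if (!is.null(config$tf_list)) {
           readLines(config$tf_list)
         } else NULL)
  })
  cp <- pick(config, c("unmeth_cut", "meth_cut", "min_nonmissing"),
             classify_params)
  lp <- pick(config, c("active_cut", "inactive_cut", "min_group", "n_perm",
                       "seed", "alpha", "method"), link_params)
  fit <- stage("pipeline", tenet(
    betas = inputs$betas, expr = inputs$expr, sheet = inputs$sheet,
    manifest = inputs$manifest, enhancers = inputs$enhancers,
    open_peaks = inputs$open_peaks, tss = inputs$tss,
    classify_params = cp, link_params = lp,
    min_dist = config$min_dist %||% 1500, tf_list = inputs$tf_list))

  stage("write", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) write.table(df, file.path(out_dir, f),
                                      sep = "\t", quote = FALSE,
                                      row.names = FALSE)
    wt(fit$classification, "classes.tsv")
    hh <- fit$classification
    diff <- hh[hh$class %in% c("hypo", "hyper"), "probe_id"]
    uni <- fit$universe
    db <- uni[uni$probe_id %in% diff, , drop = FALSE]
    write_bed(genomic_intervals(db$chrom, db$pos, db$pos + 1,
                                db$probe_id),
              file.path(out_dir, "differential_probes.bed"))
    wt(fit$links, "links.tsv")
    wt(fit$hubs, "hubs.tsv")
    wt(fit$distance_hist, "distance_hist.tsv")
    states <- fit$link_states
    if (!is.null(states) && nrow(states)) {
      write_matrix(states, file.path(out_dir, "link_states.tsv"),
                   id_col = "link")
    }
    manifest <- list(
      package = "tenet",
      version = as.character(utils::packageVersion("tenet")),
      seed = lp$seed,
      config_hash = config_hash(config),
      counts = list(
        probes_in = nrow(inputs$manifest),
        universe = nrow(fit$universe),
        classified = nrow(fit$classification),
        class_counts = as.list(fit$class_counts),
        pairs_tested = nrow(fit$links),
        links_significant = sum(fit$links$significant)))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(out_dir, "run_manifest.json"))
  })
  invisible(fit)
}

config_hash <- function(config) {
  flat <- config[order(names(config))]
  s <- paste(names(flat), vapply(flat, function(x)
    paste(as.character(x), collapse = ","), ""), sep = "=", collapse = ";")
  # small deterministic polynomial hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
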