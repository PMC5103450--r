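# Shared in-code fixtures.

# constant-valued beta matrix: one row per probe spec, groups of equal size
make_beta_fixture <- function(spec, n_per_group = 6L) {
  samples <- c(sprintf("T%02d", seq_len(n_per_group)),
               sprintf("N%02d", seq_len(n_per_group)),
               sprintf("C%02d", seq_len(n_per_group)))
  sheet <- data.frame(
    sample_id = samples,
    group = rep(c("tumor", "normal", "control"), each = n_per_group),
    stringsAsFactors = FALSE)
  m <- matrix(NA_real_, nrow(spec), length(samples),
              dimnames = list(spec$probe_id, samples))
  for (r in seq_len(nrow(spec))) {
    m[r, sheet$group == "tumor"] <- spec$tumor[r]
    m[r, sheet$group == "normal"] <- spec$normal[r]
    m[r, sheet$group == "control"] <- spec$control[r]
  }
  list(betas = m, sheet = sheet)
}

# the 12-probe truth table covering every classification branch at the
# default 0.3/0.7 thresholds (6 samples per group, min_nonmissing = 5)
truth_table_fixture <- function() {
  spec <- data.frame(
    probe_id = sprintf("p%02d", 1:12),
    tumor   = c(0.20, 0.80, 0.15, 0.15, 0.85, 0.85, 0.30, 0.70, 0.15,
                0.50, 0.15, 0.10),
    normal  = c(0.25, 0.90, 0.80, 0.80, 0.10, 0.10, 0.80, 0.90, 0.80,
                0.50, 0.80, 0.90),
    control = c(0.50, 0.90, 0.75, 0.10, 0.50, 0.90, 0.85, 0.50, 0.85,
                0.50, NA,   0.30),
    expected = c("always_unmeth",  # both low
                 "always_meth",    # both high
                 "hypo",           # tumor low, normal high, control high
                 "unclassified",   # hypo pattern but control low: purity veto
                 "hyper",          # tumor high, normal low, control mid
                 "unclassified",   # hyper pattern but control high: veto
                 "unclassified",   # tumor exactly at unmeth_cut: strict <
                 "unclassified",   # tumor exactly at meth_cut: strict >
                 "unclassified",   # missing-data veto (tumor n = 2 < 5)
                 "unclassified",   # intermediate everywhere
                 "unclassified",   # control column all missing: count veto
                 "hypo"),          # control exactly at unmeth_cut: not < cut
    stringsAsFactors = FALSE)
  fx <- make_beta_fixture(spec)
  # probe 9: only two observed tumor samples
  fx$betas["p09", fx$sheet$sample_id[fx$sheet$group == "tumor"][1:4]] <- NA
  list(betas = fx$betas, sheet = fx$sheet, expected = spec$expected,
       probe_id = spec$probe_id)
}

# small interval helpers
gi <- function(chrom, start, end, name = NA_character_) {
  genomic_intervals(chrom, start, end, name)
}

tss_tab <- function(chrom, tss) {
  data.frame(gene_id = sprintf("g%03d", seq_along(tss)), chrom = chrom,
             tss = tss, strand = "+", stringsAsFactors = FALSE)
}

probes_tab <- function(chrom, pos, ids = NULL) {
  data.frame(probe_id = ids %||% sprintf("cg%03d", seq_along(pos)),
             chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
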