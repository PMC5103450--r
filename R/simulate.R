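#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. The generator emulates an
#' array-methylation + RNA-seq tumor cohort with planted structure: a
#' driven tumor subgroup in which driver-coupled enhancer probes are
#' unmethylated (active), driver transcription factors whose expression
#' tracks the number of their active target enhancers, and target genes
#' shifted conditionally on their own enhancer's activity. Betas are drawn
#' from beta distributions centered at class targets (unmethylated ~ 0.1,
#' methylated ~ 0.85) and linearly mixed with a contamination profile at
#' `purity_mix`; expression is Gaussian on the log2 scale with unit
#' standard deviation, so `effect_size` is in sd units.
#'
#' @param n_chrom number of chromosomes (default 2).
#' @param chrom_length chromosome length in bases (default 5e6).
#' @param n_genes number of genes (default 300).
#' @param n_probes number of array probes, including the promoter-proximal
#'   decoys used to exercise the distal filter (default 500).
#' @param n_tumor,n_normal,n_control sample counts (defaults 100/20/20).
#' @param frac_hypo,frac_hyper,frac_always_unmeth,frac_always_meth planted
#'   class fractions of the non-decoy probes (defaults 0.25/0.2/0.25/0.2;
#'   the remainder is intermediate, i.e. unclassifiable).
#' @param beta_noise concentration of the beta-value distribution around
#'   its class target (default 30; per-sample sd about 0.05).
#' @param n_tf_drivers number of driver TFs (default 5).
#' @param targets_per_tf target enhancers/genes per driver (default 20).
#' @param driver_penetrance fraction of tumors in the driven subgroup
#'   (default 0.5).
#' @param effect_size expression shift in sd units coupled to enhancer
#'   activity (default 2).
#' @param purity_mix fraction of the contamination profile mixed into
#'   tumor betas (default 0.1).
#' @param activity_rate probability that a driver-target probe is active in
#'   a driven-subgroup tumor (default 1: deterministically active
#'   throughout the subgroup; values below 1 decouple probes from each
#'   other, which is the regime where driver hubs stand out from their
#'   targets).
#' @param frac_negative fraction of each driver's targets repressed rather
#'   than activated (negative-direction links; default 0.2).
#' @param decoy_frac fraction of probes placed within 1.5 kb of a TSS
#'   (default 0.1).
#' @param seed integer RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2, chrom_length = 5e6, n_genes = 300,
                       n_probes = 500, n_tumor = 100, n_normal = 20,
                       n_control = 20, frac_hypo = 0.25, frac_hyper = 0.2,
                       frac_always_unmeth = 0.25, frac_always_meth = 0.2,
                       beta_noise = 30, n_tf_drivers = 5,
                       targets_per_tf = 20, driver_penetrance = 0.5,
                       effect_size = 2, purity_mix = 0.1,
                       activity_rate = 1, frac_negative = 0.2,
                       decoy_frac = 0.1, seed = 1) {
  cfg <- list(n_chrom = n_chrom, chrom_length = chrom_length,
              n_genes = n_genes, n_probes = n_probes, n_tumor = n_tumor,
              n_normal = n_normal, n_control = n_control,
              frac_hypo = frac_hypo, frac_hyper = frac_hyper,
              frac_always_unmeth = frac_always_unmeth,
              frac_always_meth = frac_always_meth,
              beta_noise = beta_noise, n_tf_drivers = n_tf_drivers,
              targets_per_tf = targets_per_tf,
              driver_penetrance = driver_penetrance,
              effect_size = effect_size, purity_mix = purity_mix,
              activity_rate = activity_rate,
              frac_negative = frac_negative, decoy_frac = decoy_frac,
              seed = as.integer(seed))
  stopifnot(n_chrom >= 1, chrom_length > 0, n_genes >= 1, n_probes >= 1,
            n_tumor >= 1, n_normal >= 1, n_control >= 0,
            frac_hypo + frac_hyper + frac_always_unmeth +
              frac_always_meth <= 1,
            frac_hypo >= 0, frac_hyper >= 0, frac_always_unmeth >= 0,
            frac_always_meth >= 0, beta_noise > 0, n_tf_drivers >= 0,
            targets_per_tf >= 0, driver_penetrance >= 0,
            driver_penetrance <= 1, effect_size >= 0,
            purity_mix >= 0, purity_mix < 1,
            activity_rate > 0, activity_rate <= 1,
            frac_negative >= 0, frac_negative <= 1,
            decoy_frac >= 0, decoy_frac < 1)
  structure(cfg, class = "sim_config")
}

# class-target beta means: (tumor-when-active, tumor-when-inactive,
# normal, control)
BETA_UNMETH <- 0.1
BETA_METH <- 0.85
BETA_MID <- 0.5

# genome layout constants (bases)
BLOCK <- 24000
TSS_OFF <- 2000
ENH_OFF <- 10000
ENH_W <- 2000
PEAK_OFF <- 10400
PEAK_W <- 1200
PROBE_OFF <- 10600
PROBE_STEP <- 40
PROBES_PER_ENH <- 20L
DECOY_OFF <- 2500

#' Simulate a genome layout
#'
#' Places genes with block spacing well over 3 kb, one enhancer (with an
#' internal open-chromatin peak) per gene block at > 1.5 kb from every TSS,
#' enhancer probes inside the peaks, and a decoy probe set within 1.5 kb of
#' TSSs (inside promoter-proximal regions) so the distal filter has
#' something to remove. Deterministic given `config$seed`.
#'
#' @param config [sim_config()].
#' @return List with `tss`, `enhancers`, `open_peaks`, `manifest`
#'   (`probe_id`, `chrom`, `pos` 0-based) and `layout` (probe roles).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_decoy <- round(config$decoy_frac * config$n_probes)
  n_enh_probes <- config$n_probes - n_decoy
  if (n_enh_probes < 1) stop("no enhancer probes left after decoys")
  if (n_enh_probes > PROBES_PER_ENH * config$n_genes) {
    stop("infeasible packing: at most ", PROBES_PER_ENH * config$n_genes,
         " enhancer probes fit ", config$n_genes,
         " gene blocks; reduce n_probes or raise n_genes")
  }
  blocks_per_chrom <- ceiling(config$n_genes / config$n_chrom)
  if (blocks_per_chrom * BLOCK > config$chrom_length) {
    stop("infeasible packing: need chrom_length >= ",
         blocks_per_chrom * BLOCK, "; increase chrom_length")
  }
  g <- seq_len(config$n_genes) - 1L
  chrom <- paste0("chr", g %% config$n_chrom + 1L)
  block_start <- (g %/% config$n_chrom) * BLOCK
  tss <- data.frame(gene_id = sprintf("gene%05d", g + 1L), chrom = chrom,
                    tss = block_start + TSS_OFF,
                    strand = ifelse(g %% 2L == 0L, "+", "-"),
                    stringsAsFactors = FALSE)
  enhancers <- genomic_intervals(chrom, block_start + ENH_OFF,
                                 block_start + ENH_OFF + ENH_W,
                                 sprintf("enh%05d", g + 1L))
  open_peaks <- genomic_intervals(chrom, block_start + PEAK_OFF,
                                  block_start + PEAK_OFF + PEAK_W)
  # promoter-proximal decoy enhancers + peaks (removed by the distal filter)
  n_decoy_blocks <- min(n_decoy, config$n_genes)
  if (n_decoy_blocks > 0) {
    db <- seq_len(n_decoy_blocks) - 1L
    enhancers <- rbind(enhancers, genomic_intervals(
      chrom[db + 1L], block_start[db + 1L] + DECOY_OFF - 200,
      block_start[db + 1L] + DECOY_OFF + 200,
      sprintf("proxenh%05d", db + 1L)))
    open_peaks <- rbind(open_peaks, genomic_intervals(
      chrom[db + 1L], block_start[db + 1L] + DECOY_OFF - 100,
      block_start[db + 1L] + DECOY_OFF + 100))
  }
  i <- seq_len(n_enh_probes) - 1L
  enh_idx <- i %% config$n_genes
  slot <- i %/% config$n_genes
  probes <- data.frame(probe_id = sprintf("cg%06d", i + 1L),
                       chrom = chrom[enh_idx + 1L],
                       pos = block_start[enh_idx + 1L] + PROBE_OFF +
                         PROBE_STEP * slot,
                       role = "enhancer", stringsAsFactors = FALSE)
  if (n_decoy > 0) {
    j <- seq_len(n_decoy) - 1L
    didx <- j %% config$n_genes
    probes <- rbind(probes, data.frame(
      probe_id = sprintf("dc%06d", j + 1L), chrom = chrom[didx + 1L],
      pos = block_start[didx + 1L] + DECOY_OFF + 2 * (j %/% config$n_genes),
      role = "decoy", stringsAsFactors = FALSE))
  }
  list(tss = tss, enhancers = enhancers, open_peaks = open_peaks,
       manifest = probes[, c("probe_id", "chrom", "pos")],
       layout = probes)
}

derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + salt) %% 2147483647)
}

#' Simulate a tumor/normal/control cohort with planted links
#'
#' Draws beta and expression matrices over a [simulate_genome()] layout.
#' Non-decoy probes are partitioned into the planted methylation classes.
#' Each driver TF owns `targets_per_tf` hypo probes and target genes:
#' within the driven subgroup a target probe is active per sample with
#' probability `activity_rate`; its target gene's expression is shifted by
#' `effect_size` sd (negated for the repressed fraction) in samples where
#' the probe is active, and the driver TF's expression tracks the
#' standardized count of its active targets. Tumor betas are mixed with
#' the probe's contamination-profile mean at `purity_mix`. Hyper probes are
#' methylated in all tumors; undriven hypo probes are active in random
#' tumors, uncoupled from any gene.
#'
#' The ground truth lists every (probe, gene) pair that is dependent by
#' construction: `direct` (probe with its own target gene), `driver`
#' (probe with its driver TF) and, when `activity_rate = 1` and the driven
#' subgroup is a strict subset of tumors, `shared_subgroup` (every driven
#' probe with every shifted gene, since all driven probe states then equal
#' the subgroup indicator). With `effect_size = 0` no links are planted.
#'
#' @param config [sim_config()].
#' @param genome output of [simulate_genome()] (defaults to generating one
#'   from `config`).
#' @return List of class `tenet_sim` with `betas`, `expr`, `sheet`,
#'   `genome`, and `truth` (`probe_class`, `links`, `subgroup`, `drivers`).
#' @export
simulate_cohort <- function(config, genome = simulate_genome(config)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 13))
  tumors <- sprintf("T%03d", seq_len(config$n_tumor))
  normals <- sprintf("N%03d", seq_len(config$n_normal))
  controls <- if (config$n_control > 0) {
    sprintf("C%03d", seq_len(config$n_control))
  } else character()
  sheet <- data.frame(
    sample_id = c(tumors, normals, controls),
    group = c(rep("tumor", length(tumors)), rep("normal", length(normals)),
              rep("control", length(controls))),
    stringsAsFactors = FALSE)

  lay <- genome$layout
  enh_probes <- lay$probe_id[lay$role == "enhancer"]
  n_enh <- length(enh_probes)
  n_hypo <- round(config$frac_hypo * n_enh)
  n_hyper <- round(config$frac_hyper * n_enh)
  n_aun <- round(config$frac_always_unmeth * n_enh)
  n_amet <- round(config$frac_always_meth * n_enh)
  if (n_hypo + n_hyper + n_aun + n_amet > n_enh) {
    stop("class fractions exceed available probes")
  }
  n_targets <- config$n_tf_drivers * config$targets_per_tf
  if (n_targets > n_hypo) {
    stop("need at least ", n_targets, " hypo probes for ",
         config$n_tf_drivers, " drivers x ", config$targets_per_tf,
         " targets; raise frac_hypo or n_probes")
  }
  shuffled <- sample(enh_probes)
  cls <- rep("intermediate", n_enh)
  names(cls) <- shuffled
  idx <- 0L
  for (cl in c("hypo", "hyper", "always_unmeth", "always_meth")) {
    nn <- switch(cl, hypo = n_hypo, hyper = n_hyper,
                 always_unmeth = n_aun, always_meth = n_amet)
    if (nn > 0) cls[idx + seq_len(nn)] <- cl
    idx <- idx + nn
  }
  probe_class <- setNames(rep("decoy", nrow(lay)), lay$probe_id)
  probe_class[names(cls)] <- cls

  hypo_probes <- names(cls)[cls == "hypo"]
  target_probes <- hypo_probes[seq_len(n_targets)]
  undriven_hypo <- setdiff(hypo_probes, target_probes)

  genes <- genome$tss$gene_id
  if (n_targets + config$n_tf_drivers > length(genes)) {
    stop("not enough genes for targets + drivers")
  }
  picked <- sample(genes, n_targets + config$n_tf_drivers)
  target_genes <- if (n_targets > 0) picked[seq_len(n_targets)] else character()
  driver_genes <- if (config$n_tf_drivers > 0) {
    picked[n_targets + seq_len(config$n_tf_drivers)]
  } else character()
  driver_of_probe <- if (n_targets > 0) {
    setNames(rep(driver_genes, each = config$targets_per_tf), target_probes)
  } else setNames(character(), character())
  gene_of_probe <- setNames(target_genes, target_probes)

  n_driven <- round(config$driver_penetrance * config$n_tumor)
  driven <- sort(sample(tumors, n_driven))
  is_driven <- setNames(tumors %in% driven, tumors)

  # per-driver repressed targets (negative-direction links)
  sign_of_gene <- setNames(rep(1, n_targets), target_genes)
  if (n_targets > 0 && config$frac_negative > 0) {
    n_neg <- round(config$frac_negative * config$targets_per_tf)
    if (n_neg > 0) {
      for (d in seq_len(config$n_tf_drivers)) {
        tg <- target_genes[(d - 1L) * config$targets_per_tf +
                             seq_len(config$targets_per_tf)]
        sign_of_gene[tg[seq_len(n_neg)]] <- -1
      }
    }
  }

  # activity: probes x tumors binary
  all_probes <- lay$probe_id
  act <- matrix(0L, length(all_probes), config$n_tumor,
                dimnames = list(all_probes, tumors))
  if (length(target_probes)) {
    sub <- matrix(rbinom(length(target_probes) * n_driven, 1L,
                         config$activity_rate),
                  length(target_probes), n_driven)
    act[target_probes, driven] <- sub
  }
  if (length(undriven_hypo)) {
    rate <- config$driver_penetrance * config$activity_rate
    act[undriven_hypo, ] <- rbinom(length(undriven_hypo) * config$n_tumor,
                                   1L, rate)
  }

  # beta targets by class and context
  ctrl_target <- c(hypo = BETA_METH, hyper = BETA_MID,
                   always_unmeth = BETA_UNMETH, always_meth = BETA_METH,
                   intermediate = BETA_MID, decoy = BETA_UNMETH)
  normal_target <- c(hypo = BETA_METH, hyper = BETA_UNMETH,
                     always_unmeth = BETA_UNMETH, always_meth = BETA_METH,
                     intermediate = BETA_MID, decoy = BETA_UNMETH)
  tumor_inactive <- c(hypo = BETA_METH, hyper = BETA_METH,
                      always_unmeth = BETA_UNMETH, always_meth = BETA_METH,
                      intermediate = BETA_MID, decoy = BETA_UNMETH)

  np <- length(all_probes)
  n_samp <- nrow(sheet)
  mu <- matrix(NA_real_, np, n_samp,
               dimnames = list(all_probes, sheet$sample_id))
  pc <- probe_class[all_probes]
  mu[, tumors] <- tumor_inactive[pc]
  hypo_all <- all_probes[pc == "hypo"]
  if (length(hypo_all)) {
    m_t <- mu[hypo_all, tumors, drop = FALSE]
    m_t[act[hypo_all, , drop = FALSE] == 1L] <- BETA_UNMETH
    mu[hypo_all, tumors] <- m_t
  }
  mu[, normals] <- normal_target[pc]
  if (length(controls)) mu[, controls] <- ctrl_target[pc]

  cc <- config$beta_noise
  betas <- matrix(rbeta(length(mu), mu * cc, (1 - mu) * cc),
                  np, n_samp, dimnames = dimnames(mu))
  if (config$purity_mix > 0) {
    profile <- ctrl_target[pc]
    betas[, tumors] <- (1 - config$purity_mix) * betas[, tumors] +
      config$purity_mix * profile
  }

  # expression
  mu_g <- setNames(runif(length(genes), 4, 12), genes)
  expr <- matrix(rnorm(length(genes) * n_samp, mean = mu_g, sd = 1),
                 length(genes), n_samp,
                 dimnames = list(genes, sheet$sample_id))
  eff <- config$effect_size
  drivers_linked <- character()
  if (eff > 0 && length(target_probes)) {
    for (pjj in target_probes) {
      gj <- gene_of_probe[[pjj]]
      expr[gj, tumors] <- expr[gj, tumors] +
        eff * sign_of_gene[[gj]] * act[pjj, ]
    }
    for (d in driver_genes) {
      tp <- names(driver_of_probe)[driver_of_probe == d]
      k <- colSums(act[tp, , drop = FALSE])
      if (sd(k) > 0) {
        expr[d, tumors] <- expr[d, tumors] + eff * (k - mean(k)) / sd(k)
        drivers_linked <- c(drivers_linked, d)
      }
    }
  }

  # ground-truth links
  links <- data.frame(probe_id = character(), gene_id = character(),
                      direction = character(), kind = character(),
                      stringsAsFactors = FALSE)
  if (eff > 0 && length(target_probes)) {
    direct <- data.frame(probe_id = target_probes,
                         gene_id = unname(gene_of_probe[target_probes]),
                         direction = ifelse(
                           sign_of_gene[gene_of_probe[target_probes]] > 0,
                           "+", "-"),
                         kind = "direct", stringsAsFactors = FALSE)
    drv <- if (length(drivers_linked)) {
      do.call(rbind, lapply(drivers_linked, function(d) {
        tp <- names(driver_of_probe)[driver_of_probe == d]
        data.frame(probe_id = tp, gene_id = d, direction = "+",
                   kind = "driver", stringsAsFactors = FALSE)
      }))
    } else NULL
    links <- rbind(direct, drv)
    if (config$activity_rate == 1 && n_driven > 0 &&
        n_driven < config$n_tumor) {
      shifted <- c(setNames(ifelse(sign_of_gene > 0, "+", "-"),
                            names(sign_of_gene)),
                   setNames(rep("+", length(drivers_linked)),
                            drivers_linked))
      shared <- expand.grid(probe_id = target_probes,
                            gene_id = names(shifted),
                            stringsAsFactors = FALSE)
      shared$direction <- unname(shifted[shared$gene_id])
      shared$kind <- "shared_subgroup"
      key <- function(x) paste(x$probe_id, x$gene_id)
      shared <- shared[!key(shared) %in% key(links), , drop = FALSE]
      links <- rbind(links, shared)
    }
  }
  rownames(links) <- NULL

  drivers_tab <- if (length(driver_genes)) {
    data.frame(driver = driver_genes,
               n_targets = config$targets_per_tf,
               stringsAsFactors = FALSE)
  } else data.frame(driver = character(), n_targets = integer())

  structure(list(
    betas = betas, expr = expr, sheet = sheet, genome = genome,
    truth = list(probe_class = probe_class, links = links,
                 subgroup = is_driven, drivers = drivers_tab,
                 activity = act, driver_of_probe = driver_of_probe,
                 gene_of_probe = gene_of_probe)),
    class = "tenet_sim")
}

#' Write a simulated dataset to disk
#'
#' Emits the file formats the pipeline reads: enhancer and open-chromatin
#' BEDs, TSS table, probe manifest (1-based), beta and expression TSVs,
#' sample sheet, and the ground-truth tables.
#'
#' @param sim [simulate_cohort()] output.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "tenet_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- sim$genome
  write_bed(g$enhancers, file.path(dir, "enhancers.bed"))
  write_bed(g$open_peaks, file.path(dir, "open_chromatin.bed"))
  tss_out <- data.frame(gene_id = g$tss$gene_id, chrom = g$tss$chrom,
                        tss_1based = g$tss$tss + 1L, strand = g$tss$strand)
  write.table(tss_out, file.path(dir, "tss.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  man <- data.frame(probe_id = g$manifest$probe_id, chrom = g$manifest$chrom,
                    pos = g$manifest$pos + 1L)
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix(sim$betas, file.path(dir, "beta.tsv"), id_col = "probe_id")
  write_matrix(sim$expr, file.path(dir, "expr.tsv"), id_col = "gene_id")
  write.table(sim$sheet, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(probe_id = names(sim$truth$probe_class),
                         class = unname(sim$truth$probe_class)),
              file.path(dir, "truth_classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$links, file.path(dir, "truth_links.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
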