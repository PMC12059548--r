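# Synthetic-data generator: expression, promoters, a second species,
# syntelog pairs and a trait vector, all with recorded ground truth so the
# downstream inference stages can be scored against known answers.

#' Simulation configuration
#'
#' Builds the configuration object consumed by all `simulate_*()` generators.
#' Defaults emulate the study design the package targets: eight stem tissue
#' fractions (phellem through mature xylem, `F1`--`F8`) with replicated
#' RNA-seq, smooth co-expression modules (a bimodal phloem+xylem module
#' mirroring master-regulator expression, unimodal peaks, monotone ramps),
#' a three-layer planted TF-to-target network whose targets carry planted
#' PWM instances within 1 kb upstream of the TSS, a second species with a
#' controlled fraction of conserved interactions, and syntelog pairs whose
#' log10 Ks values follow a mixture with a gamma-like peak.
#'
#' @param n_genes total number of genes.
#' @param n_tfs number of transcription factors (first `n_tfs` gene ids).
#'   TFs are grouped into chains of three (layers 1-3); each chain shares one
#'   module so that within-chain regulator-target pairs stay tightly
#'   correlated.
#' @param n_modules number of planted co-expression modules (>= 2).
#' @param fractions ordered tissue-fraction labels.
#' @param replicates_per_fraction replicate count per fraction (>= 1).
#' @param noise_sd per-sample Gaussian noise on the log2 scale.
#' @param noise_gene_fraction fraction of genes that are pure noise
#'   (unassigned to any module).
#' @param flat_gene_fraction share of the noise genes that are in addition
#'   flat and lowly expressed (removed by the expression filter).
#' @param promoter_length promoter window length in bp.
#' @param motif_length PWM length in bp.
#' @param motif_ids motif identifiers; defaults to one motif per TF.
#' @param consensus_strength probability mass on the consensus base in each
#'   PWM column; the remainder is spread evenly over the other bases.
#' @param planted_hit_rate_null probability that a non-target promoter
#'   receives a planted instance of a given motif.
#' @param gc background GC fraction of simulated promoters.
#' @param n_interactions number of planted TF-to-target interactions.
#' @param conservation_fraction fraction of planted interactions conserved
#'   in the second species.
#' @param nonconserved_mode how conservation is broken in species 2:
#'   `"motif_removal"` (expression kept, motif absent) or `"rewire"` (motif
#'   kept, target ortholog moved to an uncorrelated module).
#' @param wgd_fraction fraction of genes duplicated (1:2 orthogroups) in
#'   species 2, emulating a lineage-specific WGD.
#' @param ks_mixture data frame with columns `mean`, `sd`, `weight`,
#'   `event`: Gaussian mixture of log10 Ks. Defaults place a gamma-like peak
#'   at log10 Ks = 0.0128 and an older peak at 0.45.
#' @param n_pairs number of syntelog pairs to draw.
#' @param omega_meanlog,omega_sdlog log-normal parameters of omega = Ka/Ks.
#' @param tandem_fraction fraction of extra young tandem pairs appended.
#' @param syntelog_shift planted shift in conserved-motif counts for
#'   same-cluster syntelog pairs (used by the Wilcoxon power analyses).
#' @param trait_noise Gaussian noise added to the trait profile.
#' @param amplitude_range,tf_amplitude_range,baseline_range uniform ranges
#'   for gene amplitudes and log2 baselines. The defaults keep the
#'   population correlation of planted regulator-target pairs above 0.9 at
#'   `noise_sd = 0.25`.
#' @param seed integer seed; every generator derives its own stream from it.
#' @return a `woodnet_config` list.
#' @export
simulation_config <- function(n_genes = 600L,
                              n_tfs = 3L,
                              n_modules = 6L,
                              fractions = paste0("F", 1:8),
                              replicates_per_fraction = 3L,
                              noise_sd = 0.25,
                              noise_gene_fraction = 0.5,
                              flat_gene_fraction = 0.5,
                              promoter_length = 1000L,
                              motif_length = 12L,
                              motif_ids = NULL,
                              consensus_strength = 0.98,
                              planted_hit_rate_null = 0.02,
                              gc = 0.5,
                              n_interactions = 25L,
                              conservation_fraction = 0.6,
                              nonconserved_mode = c("motif_removal", "rewire"),
                              wgd_fraction = 0,
                              ks_mixture = NULL,
                              n_pairs = 600L,
                              omega_meanlog = log(0.25),
                              omega_sdlog = 0.5,
                              tandem_fraction = 0,
                              syntelog_shift = 2,
                              trait_noise = 0.25,
                              amplitude_range = c(0.8, 1.6),
                              tf_amplitude_range = c(1.0, 1.6),
                              baseline_range = c(3, 5),
                              seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_tfs <- check_count(n_tfs, "n_tfs")
  n_modules <- check_count(n_modules, "n_modules")
  replicates_per_fraction <- check_count(replicates_per_fraction,
                                         "replicates_per_fraction")
  promoter_length <- check_count(promoter_length, "promoter_length")
  motif_length <- check_count(motif_length, "motif_length", min = 2L)
  n_interactions <- check_count(n_interactions, "n_interactions", min = 0L)
  n_pairs <- check_count(n_pairs, "n_pairs")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  noise_gene_fraction <- check_prob(noise_gene_fraction, "noise_gene_fraction")
  flat_gene_fraction <- check_prob(flat_gene_fraction, "flat_gene_fraction")
  planted_hit_rate_null <- check_prob(planted_hit_rate_null,
                                      "planted_hit_rate_null")
  conservation_fraction <- check_prob(conservation_fraction,
                                      "conservation_fraction")
  wgd_fraction <- check_prob(wgd_fraction, "wgd_fraction")
  gc <- check_prob(gc, "gc")
  if (motif_length > promoter_length) {
    abort("`motif_length` may not exceed `promoter_length`")
  }
  nonconserved_mode <- match.arg(nonconserved_mode)
  if (is.null(motif_ids)) motif_ids <- sprintf("M%02d", seq_len(n_tfs))
  if (length(motif_ids) < n_tfs) {
    abort("`motif_ids` must provide at least one motif per TF")
  }
  if (is.null(ks_mixture)) {
    ks_mixture <- tibble(
      mean = c(0.0128, 0.45),
      sd = c(0.05, 0.05),
      weight = c(0.6, 0.4),
      event = c("gamma", "ancient")
    )
  }
  ks_mixture <- as_tibble(ks_mixture)
  if (!all(c("mean", "sd", "weight", "event") %in% names(ks_mixture)) ||
      nrow(ks_mixture) == 0) {
    abort("`ks_mixture` needs columns mean, sd, weight, event (>= 1 row)")
  }
  if (any(ks_mixture$sd < 0)) abort("`ks_mixture$sd` must be non-negative")
  if (abs(sum(ks_mixture$weight) - 1) > 1e-8) {
    abort("`ks_mixture$weight` must sum to 1")
  }
  if (length(fractions) < 3) abort("`fractions` must list at least 3 labels")
  structure(list(
    n_genes = n_genes, n_tfs = n_tfs, n_modules = n_modules,
    fractions = as.character(fractions),
    replicates_per_fraction = replicates_per_fraction,
    noise_sd = noise_sd, noise_gene_fraction = noise_gene_fraction,
    flat_gene_fraction = flat_gene_fraction,
    promoter_length = promoter_length, motif_length = motif_length,
    motif_ids = as.character(motif_ids),
    consensus_strength = consensus_strength,
    planted_hit_rate_null = planted_hit_rate_null, gc = gc,
    n_interactions = n_interactions,
    conservation_fraction = conservation_fraction,
    nonconserved_mode = nonconserved_mode, wgd_fraction = wgd_fraction,
    ks_mixture = ks_mixture, n_pairs = n_pairs,
    omega_meanlog = omega_meanlog, omega_sdlog = omega_sdlog,
    tandem_fraction = tandem_fraction, syntelog_shift = syntelog_shift,
    trait_noise = trait_noise,
    amplitude_range = amplitude_range,
    tf_amplitude_range = tf_amplitude_range,
    baseline_range = baseline_range,
    seed = as.integer(seed)
  ), class = "woodnet_config")
}

# Smooth profile shapes over f fraction positions, z-scored to mean 0, sd 1.
# The first shape is bimodal (phloem + xylem peaks) emulating master-regulator
# expression; the rest are staggered unimodal peaks and monotone ramps.
module_profile_library <- function(n_modules, n_fractions) {
  pos <- seq_len(n_fractions)
  peak <- function(center, width = 0.1 * n_fractions) {
    exp(-((pos - center)^2) / (2 * width^2))
  }
  rel <- function(p) 1 + p * (n_fractions - 1)
  # The first six shapes are mutually well separated (max pairwise |r| 0.45
  # on 8 fractions) so that planted modules never collapse into each other;
  # ramps and extra peaks follow for larger module counts.
  shapes <- list(
    peak(rel(0.28)) + peak(rel(0.72)),          # bimodal phloem + xylem
    peak(rel(0.02)),
    peak(rel(0.47)),
    peak(rel(0.98)),
    peak(rel(0.20)),
    peak(rel(0.27)) + peak(rel(0.90)),
    pos,                                        # monotone up
    rev(pos),                                   # monotone down
    peak(rel(0.60)),
    peak(rel(0.85))
  )
  idx <- rep(seq_along(shapes), length.out = n_modules)
  prof <- t(vapply(idx, function(i) {
    v <- shapes[[i]]
    as.numeric(scale(v))
  }, numeric(n_fractions)))
  rownames(prof) <- paste0("module", seq_len(n_modules))
  prof
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate a replicated tissue-fraction expression matrix with ground truth
#'
#' Assigned genes follow `baseline + amplitude * module_profile` on the log2
#' scale with i.i.d. Gaussian noise per sample; a configured fraction of
#' genes is pure noise (unassigned), half of them additionally flat and
#' lowly expressed. TFs share their chain's module profile so that planted
#' regulator-target pairs have population correlation >= 0.9 at
#' `noise_sd = 0.25`. Values are exported as TPM = 2^x - 1, clipped at 0.
#'
#' @param config a [simulation_config()] object.
#' @return list with `expr` (tibble: `gene` + one column per sample),
#'   `samples` (tibble: sample, fraction, replicate) and `truth`
#'   (`woodnet_truth`: module map, TF table, planted interactions, module
#'   profiles).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "woodnet_config"))
  if (config$n_modules < 2) abort("`n_modules` must be >= 2")
  nf <- length(config$fractions)
  with_seed(config$seed + 101L, {
    ids <- gene_ids(config$n_genes)
    n_noise <- round(config$noise_gene_fraction * config$n_genes)
    n_assigned <- config$n_genes - n_noise
    if (n_assigned < config$n_tfs + config$n_modules) {
      abort("too few assigned genes for the requested TFs and modules")
    }
    profiles <- module_profile_library(config$n_modules, nf)

    # TF chains of <= 3 (layers 1-3); one module per chain, round-robin.
    tf_ids <- ids[seq_len(config$n_tfs)]
    chain <- ceiling(seq_len(config$n_tfs) / 3)
    layer <- ((seq_len(config$n_tfs) - 1L) %% 3L) + 1L
    tf_module <- ((chain - 1L) %% config$n_modules) + 1L
    tfs <- tibble(
      tf = tf_ids,
      motif = config$motif_ids[seq_len(config$n_tfs)],
      family = sprintf("FAM%02d", seq_len(config$n_tfs)),
      layer = layer, chain = chain, module = tf_module
    )

    # Remaining assigned genes round-robin over modules.
    other_assigned <- ids[(config$n_tfs + 1L):n_assigned]
    module_of <- rep(NA_integer_, config$n_genes)
    names(module_of) <- ids
    module_of[tf_ids] <- tf_module
    module_of[other_assigned] <-
      ((seq_along(other_assigned) - 1L) %% config$n_modules) + 1L

    # Planted interactions: within-chain TF->TF edges first, then targets
    # sampled without replacement from each TF's module.
    interactions <- list()
    for (c_i in unique(chain)) {
      members <- tfs[tfs$chain == c_i, ]
      members <- members[order(members$layer), ]
      if (nrow(members) > 1) {
        for (j in seq_len(nrow(members) - 1L)) {
          interactions[[length(interactions) + 1L]] <- tibble(
            tf = members$tf[j], target = members$tf[j + 1L],
            motif = members$motif[j]
          )
        }
      }
    }
    interactions <- if (length(interactions)) bind_rows(interactions) else
      tibble(tf = character(), target = character(), motif = character())
    n_left <- max(0L, config$n_interactions - nrow(interactions))
    if (n_left > 0) {
      pool <- lapply(seq_len(config$n_tfs), function(i) {
        cand <- other_assigned[module_of[other_assigned] == tf_module[i]]
        sample(cand, length(cand))
      })
      used <- character()
      tf_seq <- rep(seq_len(config$n_tfs), length.out = n_left)
      extra <- vector("list", n_left)
      for (k in seq_len(n_left)) {
        i <- tf_seq[k]
        cand <- setdiff(pool[[i]], used)
        if (!length(cand)) abort("module too small for requested interactions")
        tgt <- cand[[1]]
        used <- c(used, tgt)
        extra[[k]] <- tibble(tf = tf_ids[i], target = tgt,
                             motif = tfs$motif[i])
      }
      interactions <- bind_rows(interactions, bind_rows(extra))
    }
    interactions <- head(interactions, config$n_interactions)

    # Sample design.
    samples <- tidyr::expand_grid(
      fraction = factor(config$fractions, levels = config$fractions),
      replicate = seq_len(config$replicates_per_fraction)
    ) %>%
      mutate(sample = sprintf("%s_R%d", .data$fraction, .data$replicate),
             fraction = as.character(.data$fraction)) %>%
      select("sample", "fraction", "replicate")
    frac_idx <- match(samples$fraction, config$fractions)

    amp <- runif(config$n_genes, config$amplitude_range[1],
                 config$amplitude_range[2])
    amp[seq_len(config$n_tfs)] <- runif(config$n_tfs,
                                        config$tf_amplitude_range[1],
                                        config$tf_amplitude_range[2])
    base <- runif(config$n_genes, config$baseline_range[1],
                  config$baseline_range[2])

    n_samp <- nrow(samples)
    x <- matrix(0, config$n_genes, n_samp, dimnames = list(ids, samples$sample))
    assigned_mask <- !is.na(module_of)
    for (g in which(assigned_mask)) {
      x[g, ] <- base[g] + amp[g] * profiles[module_of[g], frac_idx]
    }
    # Pure-noise genes: half wiggly around a baseline, half flat and low.
    noise_ids <- which(!assigned_mask)
    n_flat <- round(config$flat_gene_fraction * length(noise_ids))
    flat_ids <- noise_ids[seq_len(n_flat)]
    wiggly_ids <- setdiff(noise_ids, flat_ids)
    for (g in wiggly_ids) x[g, ] <- base[g] + rnorm(n_samp, 0, 1)
    for (g in flat_ids) x[g, ] <- log2(1.5) + rnorm(n_samp, 0, 0.05)
    if (config$noise_sd > 0) {
      x[assigned_mask, ] <- x[assigned_mask, ] +
        matrix(rnorm(sum(assigned_mask) * n_samp, 0, config$noise_sd),
               sum(assigned_mask), n_samp)
    }
    tpm <- pmax(2^x - 1, 0)

    truth <- structure(list(
      module_of_gene = tibble(gene = ids, module = unname(module_of)),
      tfs = tfs,
      planted_interactions = interactions,
      planted_motif_positions = NULL,
      conserved_flags = NULL,
      syntelog_truth = NULL,
      trait_driver_module = 1L,
      profiles = profiles,
      flat_genes = ids[flat_ids],
      amplitudes = setNames(amp, ids),
      config = config
    ), class = "woodnet_truth")

    list(expr = matrix_to_tibble(tpm), samples = samples, truth = truth)
  })
}

#' @export
print.woodnet_truth <- function(x, ...) {
  cat("woodnet ground truth:",
      nrow(x$module_of_gene), "genes,",
      sum(!is.na(x$module_of_gene$module)), "assigned to",
      nrow(x$profiles), "modules;",
      nrow(x$planted_interactions), "planted interactions\n")
  invisible(x)
}

#' Simulate an informative PWM library for the configured motifs
#'
#' One PWM per motif id: a random consensus with `consensus_strength`
#' probability on the consensus base per column, the remainder spread evenly.
#'
#' @param config a [simulation_config()] object.
#' @return named list of `woodnet_pwm` objects.
#' @export
simulate_pwms <- function(config) {
  stopifnot(inherits(config, "woodnet_config"))
  with_seed(config$seed + 150L, {
    out <- lapply(seq_along(config$motif_ids), function(i) {
      cons <- sample(DNA_BASES, config$motif_length, replace = TRUE)
      mat <- matrix((1 - config$consensus_strength) / 3,
                    config$motif_length, 4,
                    dimnames = list(NULL, DNA_BASES))
      mat[cbind(seq_len(config$motif_length), match(cons, DNA_BASES))] <-
        config$consensus_strength
      new_pwm(config$motif_ids[i], mat)
    })
    setNames(out, config$motif_ids)
  })
}

sample_pwm_instance <- function(pwm, mode = c("sample", "consensus")) {
  mode <- match.arg(mode)
  mat <- pwm$matrix
  if (mode == "consensus") {
    paste(DNA_BASES[apply(mat, 1, which.max)], collapse = "")
  } else {
    paste(vapply(seq_len(nrow(mat)),
                 function(i) sample(DNA_BASES, 1, prob = mat[i, ]),
                 character(1)), collapse = "")
  }
}

reverse_complement_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

plant_instance <- function(seq_chr, instance, offset, strand) {
  ins <- if (strand == "-") reverse_complement_chr(instance) else instance
  paste0(substr(seq_chr, 1, offset),
         ins,
         substr(seq_chr, offset + nchar(ins) + 1, nchar(seq_chr)))
}

#' Simulate promoter sequences with planted motif instances
#'
#' Backgrounds are i.i.d. with the configured GC fraction. Every planted
#' interaction's target receives >= 1 instance sampled from the
#' interaction's PWM at a recorded position and strand; non-target genes
#' receive instances of each motif at `planted_hit_rate_null`.
#'
#' @param config a [simulation_config()] object.
#' @param truth ground truth from [simulate_expression()].
#' @param pwms PWM library; defaults to [simulate_pwms()] on `config`.
#' @param instance_mode `"sample"` draws each instance from the PWM,
#'   `"consensus"` plants the per-column argmax string.
#' @return list with `promoters` (tibble: gene, sequence, length, clipped),
#'   `pwms`, and updated `truth` carrying `planted_motif_positions`
#'   (gene, motif, offset, strand, kind = planted/null).
#' @export
simulate_promoters <- function(config, truth, pwms = NULL,
                               instance_mode = c("sample", "consensus")) {
  stopifnot(inherits(config, "woodnet_config"),
            inherits(truth, "woodnet_truth"))
  instance_mode <- match.arg(instance_mode)
  if (is.null(pwms)) pwms <- simulate_pwms(config)
  missing <- setdiff(unique(truth$planted_interactions$motif), names(pwms))
  if (length(missing)) {
    abort(paste("PWMs missing for motifs:", paste(missing, collapse = ", ")))
  }
  if (any(vapply(pwms, function(p) nrow(p$matrix), 1L) >
          config$promoter_length)) {
    abort("motif longer than promoter")
  }
  with_seed(config$seed + 202L, {
    ids <- truth$module_of_gene$gene
    W <- config$promoter_length
    L <- config$motif_length
    probs <- c((1 - config$gc) / 2, config$gc / 2,
               config$gc / 2, (1 - config$gc) / 2)
    seqs <- vapply(ids, function(g) {
      paste(sample(DNA_BASES, W, replace = TRUE, prob = probs), collapse = "")
    }, character(1))

    placements <- list()
    true_pairs <- truth$planted_interactions %>%
      distinct(.data$target, .data$motif)
    # Null planting first so a true instance is never overwritten.
    if (config$planted_hit_rate_null > 0) {
      for (m in names(pwms)) {
        is_true <- ids %in% true_pairs$target[true_pairs$motif == m]
        hit <- runif(length(ids)) < config$planted_hit_rate_null & !is_true
        for (g in ids[hit]) {
          off <- sample.int(W - L + 1L, 1L) - 1L
          strand <- sample(c("+", "-"), 1L)
          inst <- sample_pwm_instance(pwms[[m]], instance_mode)
          seqs[[g]] <- plant_instance(seqs[[g]], inst, off, strand)
          placements[[length(placements) + 1L]] <-
            tibble(gene = g, motif = m, offset = off, strand = strand,
                   kind = "null")
        }
      }
    }
    occupied <- list()
    for (k in seq_len(nrow(true_pairs))) {
      g <- true_pairs$target[k]; m <- true_pairs$motif[k]
      spans <- occupied[[g]]
      for (try in 1:50) {
        off <- sample.int(W - L + 1L, 1L) - 1L
        ok <- is.null(spans) ||
          all(off + L <= spans[, 1] | off >= spans[, 2])
        if (ok) break
      }
      occupied[[g]] <- rbind(spans, c(off, off + L))
      strand <- sample(c("+", "-"), 1L)
      inst <- sample_pwm_instance(pwms[[m]], instance_mode)
      seqs[[g]] <- plant_instance(seqs[[g]], inst, off, strand)
      placements[[length(placements) + 1L]] <-
        tibble(gene = g, motif = m, offset = off, strand = strand,
               kind = "planted")
    }
    truth$planted_motif_positions <- if (length(placements)) {
      bind_rows(placements)
    } else {
      tibble(gene = character(), motif = character(), offset = integer(),
             strand = character(), kind = character())
    }
    promoters <- tibble(gene = ids, sequence = unname(seqs),
                        length = nchar(unname(seqs)), clipped = FALSE)
    list(promoters = promoters, pwms = pwms, truth = truth)
  })
}

#' Simulate a second species with a controlled conserved fraction
#'
#' Every gene gets one ortholog (1:1 orthogroups; a `wgd_fraction` of genes
#' gets two copies, emulating a lineage-specific WGD). A fixed count
#' `round(conservation_fraction * n_interactions)` of planted interactions
#' is flagged conserved: their ortholog pairs keep the module profile and
#' the target ortholog keeps the binding motif. Non-conserved interactions
#' are broken per `nonconserved_mode`: `"motif_removal"` keeps the
#' correlation but drops the motif; `"rewire"` keeps the motif but moves the
#' target ortholog to a different module profile.
#'
#' @inheritParams simulate_promoters
#' @return list with `expr2`, `samples2`, `promoters2`, `orthogroups`
#'   (tibble: orthogroup, species1, species2 with comma-separated members)
#'   and updated `truth` carrying `conserved_flags`.
#' @export
simulate_second_species <- function(config, truth, pwms = NULL) {
  stopifnot(inherits(config, "woodnet_config"),
            inherits(truth, "woodnet_truth"))
  if (is.null(pwms)) pwms <- simulate_pwms(config)
  with_seed(config$seed + 303L, {
    ids <- truth$module_of_gene$gene
    module_of <- setNames(truth$module_of_gene$module, ids)
    ortho1 <- setNames(sub("^G", "S2G", ids), ids)
    dup <- runif(length(ids)) < config$wgd_fraction
    nf <- length(config$fractions)
    profiles <- truth$profiles

    ints <- truth$planted_interactions
    n_cons <- round(config$conservation_fraction * nrow(ints))
    cons_idx <- sample(nrow(ints), n_cons)
    conserved <- rep(FALSE, nrow(ints)); conserved[cons_idx] <- TRUE
    truth$conserved_flags <- ints %>%
      mutate(conserved = conserved, mode = config$nonconserved_mode)

    # Species-2 module map; rewire moves non-conserved target orthologs.
    module2 <- module_of
    if (config$nonconserved_mode == "rewire") {
      broken <- unique(ints$target[!conserved])
      module2[broken] <- (module_of[broken] %% config$n_modules) + 1L
    }

    genes2 <- unname(ortho1)
    map2 <- setNames(module2, genes2)   # species-2 gene -> module
    if (any(dup)) {
      extra <- paste0(ortho1[dup], "b")
      genes2 <- c(genes2, extra)
      map2 <- c(map2, setNames(module2[dup], extra))
    }

    samples2 <- tidyr::expand_grid(
      fraction = factor(config$fractions, levels = config$fractions),
      replicate = seq_len(config$replicates_per_fraction)
    ) %>%
      mutate(sample = sprintf("%s_R%d", .data$fraction, .data$replicate),
             fraction = as.character(.data$fraction)) %>%
      select("sample", "fraction", "replicate")
    frac_idx <- match(samples2$fraction, config$fractions)
    n_samp <- nrow(samples2)

    amp <- runif(length(genes2), config$amplitude_range[1],
                 config$amplitude_range[2])
    tf2 <- unname(ortho1[truth$tfs$tf])
    amp[match(tf2, genes2)] <- runif(length(tf2),
                                     config$tf_amplitude_range[1],
                                     config$tf_amplitude_range[2])
    base <- runif(length(genes2), config$baseline_range[1],
                  config$baseline_range[2])
    x <- matrix(0, length(genes2), n_samp,
                dimnames = list(genes2, samples2$sample))
    for (g in seq_along(genes2)) {
      m <- map2[[genes2[g]]]
      x[g, ] <- if (is.na(m)) base[g] + rnorm(n_samp, 0, 1) else
        base[g] + amp[g] * profiles[m, frac_idx]
    }
    if (config$noise_sd > 0) {
      x <- x + matrix(rnorm(length(x), 0, config$noise_sd), nrow(x))
    }
    tpm2 <- pmax(2^x - 1, 0)

    # Species-2 promoters: background + planted motifs for targets whose
    # interaction keeps its motif, + the null rate everywhere else.
    W <- config$promoter_length; L <- config$motif_length
    probs <- c((1 - config$gc) / 2, config$gc / 2,
               config$gc / 2, (1 - config$gc) / 2)
    seqs <- vapply(genes2, function(g) {
      paste(sample(DNA_BASES, W, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
    keep_motif <- conserved | config$nonconserved_mode == "rewire"
    plant2 <- ints[keep_motif, ] %>%
      mutate(target2 = unname(ortho1[.data$target])) %>%
      distinct(.data$target2, .data$motif)
    for (m in names(pwms)) {
      is_true <- genes2 %in% plant2$target2[plant2$motif == m]
      hit <- runif(length(genes2)) < config$planted_hit_rate_null & !is_true
      for (g in genes2[hit]) {
        off <- sample.int(W - L + 1L, 1L) - 1L
        inst <- sample_pwm_instance(pwms[[m]])
        seqs[[g]] <- plant_instance(seqs[[g]], inst, off, sample(c("+", "-"), 1))
      }
    }
    for (k in seq_len(nrow(plant2))) {
      g <- plant2$target2[k]
      off <- sample.int(W - L + 1L, 1L) - 1L
      inst <- sample_pwm_instance(pwms[[plant2$motif[k]]])
      seqs[[g]] <- plant_instance(seqs[[g]], inst, off, sample(c("+", "-"), 1))
    }
    promoters2 <- tibble(gene = genes2, sequence = unname(seqs),
                         length = nchar(unname(seqs)), clipped = FALSE)

    orthogroups <- tibble(
      orthogroup = sprintf("OG%06d", seq_along(ids)),
      species1 = ids,
      species2 = ifelse(dup, paste(ortho1, paste0(ortho1, "b"), sep = ", "),
                        ortho1)
    )
    list(expr2 = matrix_to_tibble(tpm2), samples2 = samples2,
         promoters2 = promoters2, orthogroups = orthogroups, truth = truth)
  })
}

#' Simulate syntelog pairs with a log10 Ks mixture
#'
#' log10(Ks) is drawn from the configured Gaussian mixture (gamma-like peak
#' by default); Ka = Ks * omega with omega log-normal. Optionally appends
#' young tandem pairs and attaches per-pair conserved-motif counts with a
#' planted shift for same-cluster pairs (for the Wilcoxon analyses).
#'
#' @param config a [simulation_config()] object.
#' @param motif_counts if `TRUE`, add `group` (same_cluster /
#'   different_cluster / unclustered) and Poisson conserved-motif counts
#'   with `syntelog_shift` added for same-cluster pairs.
#' @return tibble: gene_a, gene_b, Ks, Ka, event, duplicate_class
#'   (+ group, conserved_motifs when requested).
#' @export
simulate_syntelogs <- function(config, motif_counts = FALSE) {
  stopifnot(inherits(config, "woodnet_config"))
  mix <- config$ks_mixture
  if (any(mix$sd < 0)) abort("negative sd in ks_mixture")
  with_seed(config$seed + 404L, {
    comp <- sample.int(nrow(mix), config$n_pairs, replace = TRUE,
                       prob = mix$weight)
    log10ks <- rnorm(config$n_pairs, mix$mean[comp], mix$sd[comp])
    ks <- 10^log10ks
    omega <- stats::rlnorm(config$n_pairs, config$omega_meanlog,
                           config$omega_sdlog)
    pairs <- tibble(
      gene_a = sprintf("P%05d_a", seq_len(config$n_pairs)),
      gene_b = sprintf("P%05d_b", seq_len(config$n_pairs)),
      Ks = ks, Ka = ks * omega,
      event = mix$event[comp],
      duplicate_class = "WGM"
    )
    n_tandem <- round(config$tandem_fraction * config$n_pairs)
    if (n_tandem > 0) {
      tks <- 10^rnorm(n_tandem, -1.2, 0.15)
      pairs <- bind_rows(pairs, tibble(
        gene_a = sprintf("T%05d_a", seq_len(n_tandem)),
        gene_b = sprintf("T%05d_b", seq_len(n_tandem)),
        Ks = tks,
        Ka = tks * stats::rlnorm(n_tandem, config$omega_meanlog,
                                 config$omega_sdlog),
        event = NA_character_, duplicate_class = "tandem"
      ))
    }
    if (motif_counts) {
      grp <- sample(c("same_cluster", "different_cluster", "unclustered"),
                    nrow(pairs), replace = TRUE, prob = c(0.2, 0.5, 0.3))
      lam <- 3
      cnt <- stats::rpois(nrow(pairs), lam) +
        ifelse(grp == "same_cluster", config$syntelog_shift, 0)
      pairs$group <- grp
      pairs$conserved_motifs <- cnt
    }
    pairs
  })
}

#' Simulate a trait profile driven by one module
#'
#' The trait (for example a percent-normalized xylan MS peak) equals the
#' driver module's profile plus Gaussian noise, one value per fraction.
#'
#' @param config a [simulation_config()] object.
#' @param truth ground truth from [simulate_expression()].
#' @param driver_module module id; defaults to `truth$trait_driver_module`.
#' @return tibble: fraction, value.
#' @export
simulate_trait <- function(config, truth, driver_module = NULL) {
  stopifnot(inherits(config, "woodnet_config"),
            inherits(truth, "woodnet_truth"))
  if (is.null(driver_module)) driver_module <- truth$trait_driver_module
  if (!driver_module %in% seq_len(nrow(truth$profiles))) {
    abort(sprintf("unknown module id %s", driver_module))
  }
  with_seed(config$seed + 505L, {
    tibble(
      fraction = config$fractions,
      value = truth$profiles[driver_module, ] +
        rnorm(length(config$fractions), 0, config$trait_noise)
    )
  })
}
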