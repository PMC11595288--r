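#' The 41-analyte Luminex cytokine panel
#'
#' Names of the inflammatory and immune-response mediators measured in the
#' culture supernatants (combined 33-plex chemokine and 8-plex growth-factor
#' kits; FGF basic appears in both and is counted once).
#'
#' @param aliases if TRUE return the two-column data.frame (analyte, alias).
#' @return character vector of 41 analyte ids, or a data.frame.
#' @export
cytokine_panel <- function(aliases = FALSE) {
  path <- system.file("extdata", "cytokine_panel.tsv", package = "hemanet")
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (aliases) df else df$analyte
}

#' Configuration for the synthetic hematopoiesis dataset
#'
#' The generator emulates the structure the analysis assumes: 4 unilineage
#' cultures x 3 stages, ~1000 miRNA features with sparse lineage signatures
#' (about 100 for E, 70 for the other lineages, 50 common to all four) whose
#' CD34+ displacements are predominantly negative, 41 cytokine analytes with
#' predominantly positive displacements, and planted near-perfect negative
#' miRNA-cytokine couplings organised into modules.
#'
#' @param n_mirna number of miRNA features.
#' @param n_cytokine number of cytokine analytes (41 uses the real panel ids).
#' @param replicates replicates per (lineage, stage) condition.
#' @param n_signature named vector of per-lineage signature sizes.
#' @param n_shared signature miRNAs common to all four lineages.
#' @param effect_range range of |log2 fold change| reached by T3 for
#'   signature miRNAs.
#' @param frac_negative_mirna fraction of signature miRNA T3 displacements
#'   that are negative.
#' @param frac_positive_cytokine fraction of cytokine T3 displacements that
#'   are positive.
#' @param n_modules number of planted miRNA-cytokine modules.
#' @param module_mirnas miRNAs per module (drawn from the shared set).
#' @param module_cytokines cytokines per module.
#' @param rho planted coupling correlation, in [-1, -0.9]; -1 makes every
#'   planted pair exactly anti-linear in the noise-free limit.
#' @param coupling_range magnitude range of the negative coupling slope
#'   linking a coupled cytokine's log2 concentration to its module's stage
#'   profile; the realised T3 displacement is slope x |profile(T3)|. A
#'   narrow range keeps the three modules' coupled variance balanced, which
#'   guarantees a positive within-lineage cross-stage covariance in the
#'   cytokine space.
#' @param noise_sd observation noise sd on the log2 scale.
#' @param stage_profile monotone fractions of the T3 effect reached at
#'   (T1, T2, T3); the default accelerating profile reflects displacement
#'   amplitudes that build up late in differentiation.
#' @param stage_drift_sd sd of the lineage-shared, stage-specific miRNA
#'   drift that emulates the global (lineage-independent) maturation
#'   programme; it makes between-lineage same-stage profiles resemble each
#'   other more than consecutive stages of one lineage, the hallmark of the
#'   miRNA "force field". Drawn uniform on `[-sd*sqrt(3), sd*sqrt(3)]` so the
#'   background displacement amplitude is hard-bounded well below signature
#'   effect sizes.
#' @param cytokine_baseline_sd spread (log2) of baseline concentrations
#'   across analytes; shared by all samples, it sets the globally positive
#'   correlation floor of the cytokine space.
#' @param cytokine_offset_mean,cytokine_offset_sd lineage-specific stable
#'   secretion offset (log2) of non-coupled cytokines; it carries the
#'   lineage identity of the cytokine "state space".
#' @param cytokine_jitter_sd per-stage jitter (log2) of non-coupled
#'   cytokines.
#' @param seed master seed; it fully determines the output.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_mirna = 1000,
                             n_cytokine = 41,
                             replicates = 1,
                             n_signature = c(E = 100, Mo = 70, G = 70, Mk = 70),
                             n_shared = 50,
                             effect_range = c(3, 6),
                             frac_negative_mirna = 0.8,
                             frac_positive_cytokine = 0.8,
                             n_modules = 3,
                             module_mirnas = 8,
                             module_cytokines = 12,
                             rho = -1,
                             coupling_range = c(2, 3),
                             noise_sd = 0.1,
                             stage_profile = c(0.2, 0.5, 1),
                             stage_drift_sd = 0.85,
                             cytokine_baseline_sd = 1.2,
                             cytokine_offset_mean = 0.3,
                             cytokine_offset_sd = 1.2,
                             cytokine_jitter_sd = 1.5,
                             seed = 1) {
  stopifnot(setequal(names(n_signature), LINEAGES))
  n_signature <- n_signature[LINEAGES]
  if (n_shared > min(n_signature)) {
    stop("n_shared must not exceed the smallest per-lineage signature size")
  }
  if (n_modules * module_mirnas > n_shared) {
    stop("module miRNAs exceed the shared signature set")
  }
  if (n_modules * module_cytokines > n_cytokine) {
    stop("module cytokines exceed the cytokine panel")
  }
  if (rho < -1 || rho > -0.9) stop("rho must lie in [-1, -0.9]")
  if (max(n_signature) + n_modules * module_mirnas > n_mirna) {
    stop("signature sizes exceed n_mirna")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(stage_profile) != 3 || is.unsorted(stage_profile) ||
      any(stage_profile <= 0)) {
    stop("stage_profile must be 3 positive non-decreasing fractions")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# run expr under a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Equiangular orthonormal trio of stage profiles over (T0, T1, T2, T3).
# Each latent is centered, unit norm, mutually orthogonal, and keeps a fixed
# angle (cos = 1/sqrt(3)) to the linear ramp, so module trajectories are
# mutually uncorrelated and only moderately correlated with plain monotone
# signature ramps.
latent_trio <- function(theta, profile = c(0.15, 0.4, 1)) {
  ramp <- c(0, profile)
  r <- ramp - mean(ramp)
  r <- r / sqrt(sum(r^2))
  # orthonormal complement of r within the centered (sum-zero) subspace
  basis <- qr.Q(qr(cbind(rep(1, 4), r, diag(4))))[, 3:4]
  lat <- sapply(0:2, function(m) {
    a <- theta + 2 * pi * m / 3
    sqrt(1 / 3) * r + sqrt(2 / 3) * (cos(a) * basis[, 1] + sin(a) * basis[, 2])
  })
  # anchor at T0 (logFC of the ancestor is 0) and force a negative T3 value
  traj <- sweep(lat, 2, lat[1, ])
  sweep(traj, 2, ifelse(traj[4, ] < 0, 1, -1), "*")
}

# signed T3 effects: exactly ceiling(frac * n) negative, magnitudes uniform
draw_effects <- function(n, range, frac_negative) {
  mag <- runif(n, range[1], range[2])
  sgn <- rep(1, n)
  if (n > 0) sgn[seq_len(ceiling(frac_negative * n))] <- -1
  mag * sample(sgn)
}

#' Generate a synthetic miRNA/cytokine differentiation dataset
#'
#' Signature miRNAs follow linear log2 ramps from 0 (CD34+) to their drawn T3
#' effect; planted-module miRNAs instead follow module-specific stage
#' profiles (mutually uncorrelated across modules) so that the planted
#' couplings are identifiable. Cytokines coupled to a module trace a
#' negatively scaled copy of its profile on the log2 concentration scale: at
#' `noise_sd = 0` and `rho = -1` every planted miRNA-cytokine pair has
#' Pearson r exactly -1 over a lineage's stage series.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `mirna`, `cytokine` (abundance tables),
#'   `mirna_reference`, `cytokine_reference`, and `truth` (per-lineage
#'   signature sets, planted edge list, planted module partition, config).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  mirna_ids <- sprintf("miR-%04d", seq_len(cf$n_mirna))
  cyt_ids <- if (cf$n_cytokine == 41) cytokine_panel() else
    sprintf("CYT-%02d", seq_len(cf$n_cytokine))
  n_stage <- length(STAGES)
  ramp <- cf$stage_profile

  # --- structural draws (stream 1) ------------------------------------------
  st <- with_seed(cf$seed, {
    shared <- sample(mirna_ids, cf$n_shared)
    module_mirna <- split(shared[seq_len(cf$n_modules * cf$module_mirnas)],
                          rep(seq_len(cf$n_modules), each = cf$module_mirnas))
    plain_shared <- setdiff(shared, unlist(module_mirna))
    remaining <- setdiff(mirna_ids, shared)
    specific <- list()
    for (L in LINEAGES) {
      k <- cf$n_signature[[L]] - cf$n_shared
      specific[[L]] <- sample(remaining, k)
      remaining <- setdiff(remaining, specific[[L]])
    }
    module_cyt <- split(sample(cyt_ids, cf$n_modules * cf$module_cytokines),
                        rep(seq_len(cf$n_modules), each = cf$module_cytokines))
    list(
      shared = shared, module_mirna = module_mirna,
      plain_shared = plain_shared, specific = specific,
      module_cyt = module_cyt,
      free_cyt = setdiff(cyt_ids, unlist(module_cyt)),
      shared_effects = setNames(
        draw_effects(length(plain_shared), cf$effect_range, cf$frac_negative_mirna),
        plain_shared),
      specific_effects = lapply(setNames(LINEAGES, LINEAGES), function(L)
        setNames(draw_effects(length(specific[[L]]), cf$effect_range,
                              cf$frac_negative_mirna), specific[[L]])),
      module_amp = setNames(runif(cf$n_modules * cf$module_mirnas,
                                  cf$effect_range[1], cf$effect_range[2]),
                            unlist(module_mirna)),
      coupling = setNames(runif(cf$n_modules * cf$module_cytokines,
                                cf$coupling_range[1], cf$coupling_range[2]),
                          unlist(module_cyt)),
      theta = setNames(runif(length(LINEAGES), 0, 2 * pi), LINEAGES),
      drift = array(runif(n_stage * cf$n_mirna, -sqrt(3) * cf$stage_drift_sd,
                          sqrt(3) * cf$stage_drift_sd),
                    dim = c(n_stage, cf$n_mirna),
                    dimnames = list(STAGES, mirna_ids)),
      mirna_base = setNames(2^rnorm(cf$n_mirna, 10, 1.5), mirna_ids),
      cyt_base = setNames(rnorm(cf$n_cytokine, 5, cf$cytokine_baseline_sd),
                          cyt_ids),
      cyt_offset = array(rnorm(length(LINEAGES) * cf$n_cytokine,
                               cf$cytokine_offset_mean, cf$cytokine_offset_sd),
                         dim = c(length(LINEAGES), cf$n_cytokine),
                         dimnames = list(LINEAGES, cyt_ids)),
      cyt_jitter = array(rnorm(length(LINEAGES) * n_stage * cf$n_cytokine,
                               0, cf$cytokine_jitter_sd),
                         dim = c(length(LINEAGES), n_stage, cf$n_cytokine),
                         dimnames = list(LINEAGES, STAGES, cyt_ids)),
      decouple = array(rnorm(length(LINEAGES) * n_stage * cf$n_cytokine),
                       dim = c(length(LINEAGES), n_stage, cf$n_cytokine),
                       dimnames = list(LINEAGES, STAGES, cyt_ids))
    )
  })

  # noise-free log2 signal per lineage: stages x features
  mirna_signal <- function(L) {
    sig <- matrix(0, n_stage, cf$n_mirna, dimnames = list(STAGES, mirna_ids))
    eff <- c(st$shared_effects, st$specific_effects[[L]])
    sig[, names(eff)] <- outer(ramp, eff)
    traj <- latent_trio(st$theta[[L]], cf$stage_profile)   # 4 x n_modules, rows T0..T3
    for (m in seq_len(cf$n_modules)) {
      ids <- st$module_mirna[[m]]
      amp <- st$module_amp[ids] / max(abs(traj[, m]))
      sig[, ids] <- outer(traj[-1, m], amp)
    }
    sig
  }
  cyt_signal <- function(L) {
    sig <- matrix(0, n_stage, cf$n_cytokine, dimnames = list(STAGES, cyt_ids))
    traj <- latent_trio(st$theta[[L]], cf$stage_profile)
    for (m in seq_len(cf$n_modules)) {
      ids <- st$module_cyt[[m]]
      scale <- -st$coupling[ids]                # negative slope; traj[T3] < 0
      coupled <- outer(traj[-1, m], scale)      # => positive T3 displacement
      if (cf$rho > -1) {
        # dilute the coupling with an independent component sized to the
        # target correlation (exact in expectation over the jitter)
        lam <- sqrt(1 / cf$rho^2 - 1) * sqrt(mean(traj[-1, m]^2))
        coupled <- coupled + sweep(st$decouple[L, , ids], 2,
                                   abs(scale) * lam, "*")
      }
      sig[, ids] <- coupled
    }
    sig[, st$free_cyt] <- sweep(st$cyt_jitter[L, , st$free_cyt], 2,
                                st$cyt_offset[L, st$free_cyt], "+")
    # coupled displacements are positive at T3 by construction; if they alone
    # cannot cover the configured positive fraction, flip enough free-analyte
    # trajectories to honour it
    n_need <- ceiling(cf$frac_positive_cytokine * cf$n_cytokine) -
      cf$n_modules * cf$module_cytokines
    if (n_need > 0) {
      force_pos <- st$free_cyt[seq_len(min(n_need, length(st$free_cyt)))]
      flip <- force_pos[sig[n_stage, force_pos] < 0]
      sig[, flip] <- -sig[, flip, drop = FALSE]
    }
    sig
  }

  cols <- unlist(lapply(LINEAGES, function(L)
    unlist(lapply(STAGES, function(t)
      if (cf$replicates == 1) paste(L, t, sep = "_")
      else paste(L, t, seq_len(cf$replicates), sep = "_")))))

  mirna_vals <- {
    vals <- matrix(NA_real_, cf$n_mirna, length(cols),
                   dimnames = list(mirna_ids, cols))
    noise <- with_seed(cf$seed + 1L,
      matrix(rnorm(length(vals), 0, cf$noise_sd), nrow(vals), ncol(vals)))
    j <- 0
    for (L in LINEAGES) {
      # the lineage-shared stage drift (global maturation programme) rides on
      # the background features only: a lineage's own signature and module
      # trajectories are governed by its differentiation programme
      drift <- st$drift
      own <- c(names(st$shared_effects), names(st$specific_effects[[L]]),
               unlist(st$module_mirna))
      drift[, own] <- 0
      sig <- mirna_signal(L) + drift
      for (t in seq_len(n_stage)) for (r in seq_len(cf$replicates)) {
        j <- j + 1
        vals[, j] <- 2^(log2(st$mirna_base) + sig[t, ] + noise[, j])
      }
    }
    vals
  }
  cyt_vals <- {
    vals <- matrix(NA_real_, cf$n_cytokine, length(cols),
                   dimnames = list(cyt_ids, cols))
    noise <- with_seed(cf$seed + 2L,
      matrix(rnorm(length(vals), 0, cf$noise_sd), nrow(vals), ncol(vals)))
    j <- 0
    for (L in LINEAGES) {
      sig <- cyt_signal(L)
      for (t in seq_len(n_stage)) for (r in seq_len(cf$replicates)) {
        j <- j + 1
        vals[, j] <- 2^(st$cyt_base + sig[t, ] + noise[, j])
      }
    }
    vals
  }

  edges <- do.call(rbind, lapply(seq_len(cf$n_modules), function(m)
    expand.grid(mirna = st$module_mirna[[m]], cytokine = st$module_cyt[[m]],
                module = m, rho = cf$rho, stringsAsFactors = FALSE)))
  modules <- c(
    setNames(rep(seq_len(cf$n_modules), each = cf$module_mirnas),
             unlist(st$module_mirna)),
    setNames(rep(seq_len(cf$n_modules), each = cf$module_cytokines),
             unlist(st$module_cyt))
  )
  signatures <- lapply(setNames(LINEAGES, LINEAGES), function(L)
    sort(c(st$shared, st$specific[[L]])))

  list(
    mirna = abundance_table(mirna_vals, "miRNA"),
    cytokine = abundance_table(cyt_vals, "cytokine"),
    mirna_reference = reference_profile(st$mirna_base, "miRNA"),
    cytokine_reference = reference_profile(setNames(2^st$cyt_base, cyt_ids),
                                           "cytokine"),
    truth = list(signatures = signatures, edges = edges, modules = modules,
                 shared = st$shared, config = cf)
  )
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b membership vectors over the same elements (matched by name when
#'   both are named, else by position).
#' @return ARI in [-1, 1]; 1 iff the partitions are identical up to
#'   relabelling.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) == 0) stop("no common elements between partitions")
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b)) stop("partitions cover different universes")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(ifelse(nij == expected, 1, 0))
  (nij - expected) / (maxi - expected)
}

# precision/recall of a set against a reference set
set_pr <- function(inferred, truth) {
  tp <- length(intersect(inferred, truth))
  c(precision = if (length(inferred)) tp / length(inferred) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_)
}

#' Score inferred results against the planted ground truth
#'
#' @param truth the `truth` element returned by [generate_dataset()].
#' @param signatures optional named list of per-lineage selected miRNA ids.
#' @param edges optional data.frame with columns `mirna`, `cytokine` of
#'   inferred network edges. When a `lineage` column is present, edges are
#'   scored per (lineage, miRNA, cytokine) instance against the planted
#'   couplings replicated over the lineages observed (each lineage's network
#'   is a separate inference); otherwise pairs are deduplicated and scored
#'   once.
#' @param partition optional named membership vector (node id -> community);
#'   scored by adjusted Rand index against the planted module partition,
#'   restricted to the planted module members.
#' @return list of scores in [0, 1] (ARI can be slightly negative for
#'   worse-than-chance partitions).
#' @export
recovery_report <- function(truth, signatures = NULL, edges = NULL,
                            partition = NULL) {
  out <- list()
  if (!is.null(signatures)) {
    per <- sapply(LINEAGES, function(L) {
      if (is.null(signatures[[L]])) return(c(precision = NA, recall = NA))
      set_pr(signatures[[L]], truth$signatures[[L]])
    })
    out$signature <- list(per_lineage = per,
                          precision = mean(per["precision", ], na.rm = TRUE),
                          recall = mean(per["recall", ], na.rm = TRUE))
  }
  if (!is.null(edges)) {
    if (!is.null(edges$lineage)) {
      lins <- unique(edges$lineage)
      key_inf <- unique(paste(edges$lineage, edges$mirna, edges$cytokine,
                              sep = "~"))
      key_true <- as.vector(outer(lins,
        paste(truth$edges$mirna, truth$edges$cytokine, sep = "~"),
        paste, sep = "~"))
      out$edges <- as.list(set_pr(key_inf, key_true))
    } else {
      key <- function(df) unique(paste(df$mirna, df$cytokine, sep = "~"))
      out$edges <- as.list(set_pr(key(edges), key(truth$edges)))
    }
  }
  if (!is.null(partition)) {
    out$module_ari <- adjusted_rand_index(partition, truth$modules)
  }
  out
}
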