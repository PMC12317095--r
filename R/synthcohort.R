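# Synthetic paired-modality cohorts.
#
# Real paired H&E/IHC slide archives with linked molecular calls and claims
# data are not publicly distributable, so the package ships a generator that
# emulates their structure: per-case tile-embedding bags for two stain
# modalities with a planted biomarker signal, label-generating assay
# measurements (microsatellite locus counts or PD-L1 cell counts), scanner
# and specimen-site covariate shifts, and claims-style treatment/outcome
# tables. Every downstream stage of the pipeline is exercised against these
# cohorts.

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions under which synthetic paired-modality
#' cohorts are drawn. Positive cases carry a mean-shift signal in a small,
#' modality-specific embedding subspace on a fraction of their tiles; each
#' modality expresses the signal independently with probability
#' `expression_prob`, so single-stain information is deliberately incomplete
#' while the two stains together are nearly complete (the "complementary
#' signal" design). Scanner and site shifts live in a nuisance subspace
#' disjoint from both signal blocks.
#'
#' @param n_cases number of cases.
#' @param prevalence probability a case is biomarker-positive.
#' @param tiles_per_slide_range integer range (min, max) of tiles per slide.
#' @param signal_fraction fraction of tiles carrying signal in expressing
#'   positive slides.
#' @param d_sig dimension of each modality's signal block.
#' @param effect_he,effect_ihc mean shifts (length `d_sig`) applied in the
#'   H&E block (coordinates `1:d_sig`) and the IHC block
#'   (`(d_sig+1):(2*d_sig)`).
#' @param expression_prob probability each modality of a positive case
#'   expresses its signal (drawn independently per modality; resampled so at
#'   least one modality expresses).
#' @param embed_dim embedding width (default 768, matching the tile-encoder
#'   contract).
#' @param noise_sd standard deviation of the isotropic embedding noise.
#' @param scanner_shift,site_shift norms of the additive covariate offset
#'   vectors applied to slides from the second scanner / metastatic site.
#' @param site_noise_sd extra noise standard deviation added to metastatic
#'   slides (default 0; used to study stratified performance).
#' @param assay `"MSI_LOCI"` (altered-locus counts) or `"CPS"` (PD-L1
#'   combined positive score cell counts).
#' @param equivocal_rate rate at which equivocal measurements (loci 113-115)
#'   are generated; such cases are excluded before modelling.
#' @param outcome_params list of claims/outcome parameters, see
#'   [simulate_outcomes()].
#' @param seed integer; the same seed reproduces the cohort exactly.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_cases = 300,
                         prevalence = 0.3,
                         tiles_per_slide_range = c(10L, 40L),
                         signal_fraction = 0.3,
                         d_sig = 16,
                         effect_he = rep(2, d_sig),
                         effect_ihc = rep(2, d_sig),
                         expression_prob = 0.7,
                         embed_dim = 768,
                         noise_sd = 1,
                         scanner_shift = 0.5,
                         site_shift = 0.5,
                         site_noise_sd = 0,
                         assay = c("MSI_LOCI", "CPS"),
                         equivocal_rate = 0,
                         outcome_params = .default_outcome_params(),
                         seed = 1L) {
  assay <- match.arg(assay)
  if (!is_count(n_cases) || n_cases < 1) stopf("n_cases must be a positive count")
  if (!is_prob(prevalence)) stopf("prevalence must lie in [0, 1]")
  if (!is_prob(signal_fraction)) stopf("signal_fraction must lie in [0, 1]")
  if (!is_prob(expression_prob)) stopf("expression_prob must lie in [0, 1]")
  if (!is_prob(equivocal_rate)) stopf("equivocal_rate must lie in [0, 1]")
  if (length(tiles_per_slide_range) != 2 || tiles_per_slide_range[1] < 1 ||
      tiles_per_slide_range[2] < tiles_per_slide_range[1]) {
    stopf("tiles_per_slide_range must be an increasing interval with lower bound >= 1")
  }
  if (!all(is.finite(effect_he)) || !all(is.finite(effect_ihc))) {
    stopf("effect vectors must be finite")
  }
  if (length(effect_he) != d_sig || length(effect_ihc) != d_sig) {
    stopf("effect vectors must have length d_sig")
  }
  if (embed_dim < 2 * d_sig + 2) stopf("embed_dim too small for two signal blocks plus nuisance space")
  structure(list(
    n_cases = as.integer(n_cases), prevalence = prevalence,
    tiles_per_slide_range = as.integer(tiles_per_slide_range),
    signal_fraction = signal_fraction, d_sig = as.integer(d_sig),
    effect_he = effect_he, effect_ihc = effect_ihc,
    expression_prob = expression_prob, embed_dim = as.integer(embed_dim),
    noise_sd = noise_sd, scanner_shift = scanner_shift,
    site_shift = site_shift, site_noise_sd = site_noise_sd,
    assay = assay, equivocal_rate = equivocal_rate,
    outcome_params = outcome_params, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Claims/outcome simulation parameters
#'
#' @param base_rate baseline daily hazard of death in the biomarker-negative
#'   arm (default 1/300, i.e. median survival about 208 days).
#' @param log_hr true log hazard ratio of the biomarker-positive arm
#'   (default `log(0.5)`: protective).
#' @param censor_rate daily hazard of non-informative dropout from the
#'   claims stream while alive.
#' @param tot_rate baseline daily hazard of stopping treatment; the same
#'   `log_hr` applies, so positives also stay on treatment longer.
#' @param refresh_day day index of the claims-data refresh (administrative
#'   censoring horizon).
#' @param accrual_days first administrations are spread uniformly over
#'   `[0, accrual_days]`.
#' @param p_death_recorded probability a death is present in the
#'   real-world-evidence table (unrecorded deaths must be recovered by the
#'   100-day claims-gap rule).
#' @return a list of validated parameters.
#' @export
outcome_params <- function(base_rate = 1 / 300, log_hr = log(0.5),
                           censor_rate = 1 / 2000, tot_rate = 1 / 150,
                           refresh_day = 1000L, accrual_days = 100L,
                           p_death_recorded = 0.8) {
  if (base_rate <= 0 || censor_rate <= 0 || tot_rate <= 0) {
    stopf("event rates must be positive")
  }
  if (!is_prob(p_death_recorded)) stopf("p_death_recorded must lie in [0, 1]")
  list(base_rate = base_rate, log_hr = log_hr, censor_rate = censor_rate,
       tot_rate = tot_rate, refresh_day = as.integer(refresh_day),
       accrual_days = as.integer(accrual_days),
       p_death_recorded = p_death_recorded)
}

# alias so synth_config's argument default can call the constructor without
# colliding with its own argument name
.default_outcome_params <- function() outcome_params()

#' Assign microsatellite-instability status from an altered-locus count
#'
#' Applies the locus-count rule used to call MSI from targeted sequencing of
#' microsatellite regions: 116 or more altered loci is MSI-high, 113 to 115
#' is equivocal, 112 or fewer is microsatellite stable.
#'
#' @param loci_altered non-negative integer count(s) of altered loci.
#' @return factor with levels `MSS`, `EQUIVOCAL`, `MSI_H`.
#' @export
assign_msi_label <- function(loci_altered) {
  if (any(!is.finite(loci_altered)) || any(loci_altered < 0)) {
    stopf("loci_altered must be non-negative")
  }
  out <- ifelse(loci_altered >= 116, "MSI_H",
         ifelse(loci_altered >= 113, "EQUIVOCAL", "MSS"))
  factor(out, levels = c("MSS", "EQUIVOCAL", "MSI_H"))
}

#' Combined Positive Score
#'
#' CPS = 100 x (PD-L1 positive cells, counting tumor cells, lymphocytes and
#' macrophages) / (viable tumor cells). Because the numerator includes
#' immune cells the raw ratio can exceed 1; scores are capped at 100,
#' following clinical convention.
#'
#' @param pdl1_positive_cells non-negative count(s).
#' @param viable_tumor_cells positive count(s).
#' @return numeric CPS in `[0, 100]`.
#' @export
compute_cps <- function(pdl1_positive_cells, viable_tumor_cells) {
  if (any(!is.finite(pdl1_positive_cells)) || any(pdl1_positive_cells < 0)) {
    stopf("pdl1_positive_cells must be non-negative")
  }
  if (any(!is.finite(viable_tumor_cells)) || any(viable_tumor_cells < 1)) {
    stopf("viable_tumor_cells must be >= 1")
  }
  pmin(100, 100 * pdl1_positive_cells / viable_tumor_cells)
}

#' PD-L1 positivity from CPS
#'
#' CPS of 10 or above is positive; below 10 is negative.
#'
#' @param cps numeric CPS value(s) in `[0, 100]`.
#' @return factor with levels `NEGATIVE`, `POSITIVE`.
#' @export
assign_pdl1_label <- function(cps) {
  if (any(!is.finite(cps)) || any(cps < 0) || any(cps > 100)) {
    stopf("cps must lie in [0, 100]")
  }
  factor(ifelse(cps >= 10, "POSITIVE", "NEGATIVE"),
         levels = c("NEGATIVE", "POSITIVE"))
}

# Status-conditional measurement draws. Over-dispersed counts mimic assay
# variability; rejection sampling guarantees the rule-derived label equals
# the latent status exactly.
r_msi_loci <- function(status) {
  vapply(status, function(s) {
    repeat {
      x <- if (s == 1) stats::rnbinom(1, size = 5, mu = 135) else
                       stats::rnbinom(1, size = 10, mu = 80)
      if (s == 1 && x >= 116) return(x)
      if (s == 0 && x <= 112) return(x)
    }
  }, numeric(1))
}

r_cps_counts <- function(status) {
  out <- t(vapply(status, function(s) {
    repeat {
      viable <- 1 + stats::rpois(1, 250)
      rate <- if (s == 1) 0.30 * viable else 0.03 * viable
      pos <- stats::rpois(1, rate)
      cps <- min(100, 100 * pos / viable)
      if (s == 1 && cps >= 10) return(c(pos, viable))
      if (s == 0 && cps < 10) return(c(pos, viable))
    }
  }, numeric(2)))
  colnames(out) <- c("pdl1_positive_cells", "viable_tumor_cells")
  out
}

#' Simulate claims-style outcome records
#'
#' Draws status-conditional exponential death times (hazard
#' `base_rate * exp(log_hr * status)`), independent dropout from the claims
#' stream, and administrative censoring at the claims refresh. Deaths are
#' recorded in the output with probability `p_death_recorded`; unrecorded
#' deaths leave only a claims gap, exercising the 100-day presumed-death
#' rule downstream. Treatment stop times give the on-treatment interval.
#'
#' @param status 0/1 vector of biomarker status.
#' @param params list from [outcome_params()].
#' @param seed optional integer seed.
#' @return data.frame with columns `first_admin_day`, `last_admin_day`,
#'   `last_claim_day`, `refresh_day`, `death_day` (NA when unrecorded).
#' @export
simulate_outcomes <- function(status, params = outcome_params(), seed = NULL) {
  if (params$base_rate <= 0 || params$censor_rate <= 0 || params$tot_rate <= 0) {
    stopf("event rates must be positive")
  }
  n <- length(status)
  with_seed(seed, {
    first <- sample.int(params$accrual_days + 1L, n, replace = TRUE) - 1L
    haz <- params$base_rate * exp(params$log_hr * status)
    t_death <- stats::rexp(n, haz)
    t_drop <- stats::rexp(n, params$censor_rate)
    t_admin <- params$refresh_day - first
    follow <- pmin(t_death, t_drop, t_admin)
    died <- t_death <= pmin(t_drop, t_admin)
    dropped <- !died & t_drop <= t_admin

    t_stop <- stats::rexp(n, params$tot_rate * exp(params$log_hr * status))
    last_admin <- first + floor(pmin(t_stop, follow))

    last_claim <- integer(n)
    last_claim[died] <- first[died] + floor(t_death[died])
    last_claim[dropped] <- first[dropped] + floor(t_drop[dropped])
    alive_idx <- which(!died & !dropped)
    # still in the claims stream at refresh: last contact within 100 days
    gap <- sample.int(100L, length(alive_idx), replace = TRUE) - 1L
    last_claim[alive_idx] <- params$refresh_day - gap

    last_claim <- pmin(pmax(last_claim, last_admin), params$refresh_day)
    death_day <- rep(NA_integer_, n)
    rec <- died & stats::runif(n) < params$p_death_recorded
    death_day[rec] <- first[rec] + as.integer(floor(t_death[rec]))
    data.frame(
      first_admin_day = as.integer(first),
      last_admin_day = as.integer(last_admin),
      last_claim_day = as.integer(last_claim),
      refresh_day = rep(as.integer(params$refresh_day), n),
      death_day = death_day
    )
  })
}

# Fixed unit vectors spanning the nuisance (covariate-shift) subspace,
# disjoint from both signal blocks.
covariate_vectors <- function(embed_dim, d_sig) {
  scanner <- numeric(embed_dim)
  site <- numeric(embed_dim)
  scanner[2 * d_sig + 1] <- 1
  site[2 * d_sig + 2] <- 1
  list(scanner = scanner, site = site)
}

tile_grid_boxes <- function(n, tile_size = 224L) {
  ncols <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  cbind(x0 = (idx %% ncols) * tile_size,
        y0 = (idx %/% ncols) * tile_size,
        width = rep(tile_size, n), height = rep(tile_size, n))
}

#' Generate a synthetic paired-modality cohort
#'
#' Draws `n_cases` cases with latent binary biomarker status at the
#' configured prevalence. Each case has an H&E and an IHC embedding bag
#' (`N x embed_dim` Gaussian noise); in positive cases a `signal_fraction`
#' of tiles is mean-shifted by `effect_he` / `effect_ihc` in disjoint
#' coordinate blocks, independently expressed per modality. Assay
#' measurements are drawn conditionally on status so that rule-derived
#' labels reproduce the latent status exactly, and linked claims-style
#' outcome records are attached. Scanner and site are assigned per case and
#' applied as additive offsets in a nuisance subspace.
#'
#' @param config a [synth_config()].
#' @return object of class `synth_cohort`: list with `cases` (named list)
#'   and `config`. Each case holds `status`, `label`, `measurement`,
#'   `scanner`, `site`, the two `embedding_bag`s (`he`, `ihc`), per-tile
#'   signal indicators, and an outcome record.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  d <- cfg$embed_dim
  ds <- cfg$d_sig
  he_block <- seq_len(ds)
  ihc_block <- ds + seq_len(ds)
  cov <- covariate_vectors(d, ds)

  with_seed(cfg$seed, {
    n <- cfg$n_cases
    status <- stats::rbinom(n, 1, cfg$prevalence)
    equivocal <- stats::runif(n) < cfg$equivocal_rate
    scanner <- sample(c("philips", "leica"), n, replace = TRUE)
    site <- sample(c("primary", "metastatic"), n, replace = TRUE,
                   prob = c(0.7, 0.3))

    if (cfg$assay == "MSI_LOCI") {
      loci <- r_msi_loci(status)
      loci[equivocal] <- sample(113:115, sum(equivocal), replace = TRUE)
      labels <- assign_msi_label(loci)
    } else {
      counts <- r_cps_counts(status)
      cps <- compute_cps(counts[, 1], counts[, 2])
      labels <- assign_pdl1_label(cps)
    }

    outcomes <- simulate_outcomes(status, cfg$outcome_params)

    cases <- vector("list", n)
    ids <- sprintf("case_%04d", seq_len(n))
    for (i in seq_len(n)) {
      n_tiles <- sample(seq(cfg$tiles_per_slide_range[1],
                            cfg$tiles_per_slide_range[2]), 1)
      expr_he <- expr_ihc <- FALSE
      if (status[i] == 1) {
        repeat {
          expr_he <- stats::runif(1) < cfg$expression_prob
          expr_ihc <- stats::runif(1) < cfg$expression_prob
          if (expr_he || expr_ihc) break
        }
      }
      n_sig <- max(1L, round(cfg$signal_fraction * n_tiles))
      sig_idx <- sort(sample.int(n_tiles, n_sig))

      make_mod <- function(modality, expresses, block, effect) {
        emb <- matrix(stats::rnorm(n_tiles * d, 0, cfg$noise_sd), n_tiles, d)
        sig <- rep(FALSE, n_tiles)
        if (expresses) {
          sig[sig_idx] <- TRUE
          emb[sig_idx, block] <- emb[sig_idx, block] +
            matrix(effect, n_sig, length(block), byrow = TRUE)
        }
        if (scanner[i] == "leica") {
          emb <- emb + matrix(cov$scanner * cfg$scanner_shift, n_tiles, d,
                              byrow = TRUE)
        }
        if (site[i] == "metastatic") {
          emb <- emb + matrix(cov$site * cfg$site_shift, n_tiles, d,
                              byrow = TRUE)
          if (cfg$site_noise_sd > 0) {
            emb <- emb + matrix(stats::rnorm(n_tiles * d, 0, cfg$site_noise_sd),
                                n_tiles, d)
          }
        }
        bag <- embedding_bag(ids[i], modality, emb,
                             tile_grid_boxes(n_tiles),
                             scanner = scanner[i], site = site[i])
        list(bag = bag, signal = sig)
      }
      he <- make_mod("HE", status[i] == 1 && expr_he, he_block, cfg$effect_he)
      ihc <- make_mod("IHC", status[i] == 1 && expr_ihc, ihc_block, cfg$effect_ihc)

      meas <- if (cfg$assay == "MSI_LOCI") {
        list(assay = "MSI_LOCI", loci_altered = loci[i])
      } else {
        list(assay = "CPS", pdl1_positive_cells = counts[i, 1],
             viable_tumor_cells = counts[i, 2], cps = cps[i])
      }
      cases[[i]] <- list(
        case_id = ids[i], status = status[i], label = labels[i],
        measurement = meas, scanner = scanner[i], site = site[i],
        he = he$bag, ihc = ihc$bag,
        signal_tiles_he = he$signal, signal_tiles_ihc = ihc$signal,
        outcome = outcomes[i, , drop = FALSE]
      )
    }
    names(cases) <- ids
    structure(list(cases = cases, config = cfg), class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  n <- length(x$cases)
  st <- vapply(x$cases, `[[`, numeric(1), "status")
  cat(sprintf("Synthetic paired-modality cohort: %d cases (%d positive, %.1f%%), assay %s\n",
              n, sum(st), 100 * mean(st), x$config$assay))
  invisible(x)
}

#' Drop equivocal / indeterminate cases before modelling
#'
#' @param cohort a `synth_cohort`.
#' @return the cohort with equivocal-label cases removed.
#' @export
exclude_indeterminate <- function(cohort) {
  stopifnot(inherits(cohort, "synth_cohort"))
  keep <- vapply(cohort$cases, function(cs) cs$label != "EQUIVOCAL", logical(1))
  if (!all(keep)) {
    message(sprintf("excluding %d equivocal case(s)", sum(!keep)))
    cohort$cases <- cohort$cases[keep]
  }
  cohort
}

#' Cohort manifest as a data frame
#'
#' One row per case: id, latent status, rule-derived label, measurement
#' fields, scanner, site and outcome day indices. Written as the CSV
#' interchange format by [run_pipeline()].
#'
#' @param cohort a `synth_cohort`.
#' @return data.frame.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "synth_cohort"))
  rows <- lapply(cohort$cases, function(cs) {
    m <- cs$measurement
    data.frame(
      case_id = cs$case_id, status = cs$status,
      label = as.character(cs$label), assay = m$assay,
      loci_altered = if (m$assay == "MSI_LOCI") m$loci_altered else NA,
      pdl1_positive_cells = if (m$assay == "CPS") m$pdl1_positive_cells else NA,
      viable_tumor_cells = if (m$assay == "CPS") m$viable_tumor_cells else NA,
      scanner = cs$scanner, site = cs$site,
      n_tiles_he = nrow(cs$he$embeddings),
      n_tiles_ihc = nrow(cs$ihc$embeddings),
      cs$outcome, row.names = NULL
    )
  })
  do.call(rbind, rows)
}

case_labels <- function(cohort, ids = names(cohort$cases)) {
  vapply(cohort$cases[ids], `[[`, numeric(1), "status")
}
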