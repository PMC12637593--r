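#' Specification of a synthetic cohort
#'
#' Describes a seeded cohort of synthetic cells for one of the two study
#' designs:
#'
#' * `"intrinsic"`: per cell, the two current-step families of the
#'   waveform study (-200 to 200 pA in 40 pA increments, and 200 to
#'   1200 pA in 100 pA increments; 22 sweeps).
#' * `"synaptic"`: per pair, a test-pulse sweep, single-pulse sweeps,
#'   repeated paired pulses at the seven interstimulus intervals
#'   (10, 20, 50, 100, 200, 500, 1000 ms) and 5-pulse trains.
#'
#' Genotype enters the generators through `f_het` (heteromer fraction of
#' the delayed-rectifier conductance: 0.5, 0.3, 0 for `WT/WT`, `Cre/WT`,
#' `Cre/Cre`) for intrinsic cells and through the release probability
#' `U` (0.60 wild type vs 0.45 knockout) for synaptic pairs.
#' `kcng4_fraction` sets the fraction of wild-type cells that express
#' the silent subunit at all (default 1; set ~0.35 to emulate a mixed
#' wild-type population in which only a subset of cells expresses it).
#'
#' @param design `"intrinsic"` or `"synaptic"`.
#' @param n_cells Named integer vector of cells (or pairs) per genotype,
#'   e.g. `c("WT/WT" = 18, "Cre/WT" = 16, "Cre/Cre" = 20)`.
#' @param seed Integer seed; a fixed seed makes the cohort fully
#'   reproducible (bit-identical bundles).
#' @param f_het_by_genotype,U_by_genotype Named per-genotype parameter
#'   means.
#' @param kcng4_fraction Expressing fraction among `WT/WT` cells.
#' @param cv Between-cell coefficient of variation applied to the main
#'   conductances/capacitance (intrinsic) and to the amplitude scale
#'   (synaptic).
#' @param U_sd Between-pair SD of the release probability.
#' @param delta_ts_ms Paired-pulse interstimulus intervals.
#' @param train_isis_ms 5-pulse-train interstimulus intervals (the
#'   stimulation-pattern set beyond the listed paired-pulse intervals is
#'   not enumerated in the emulated protocol, so it is configuration).
#' @param n_repeats Repeats per stimulation pattern (3-5 in the emulated
#'   protocol).
#' @param n_single Single-pulse sweeps per pair.
#' @param step_amps_pA Optional override of the intrinsic step
#'   amplitudes (both families combined).
#' @param step_duration_ms,step_onset_ms Intrinsic step timing.
#' @param dt_ms Sampling interval (0.02 ms intrinsic, 0.1 ms synaptic
#'   when `NULL`).
#' @param noise_sd_pA Noise level override (`NULL` keeps generator
#'   defaults).
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(design = c("intrinsic", "synaptic"),
                        n_cells = NULL, seed = 1,
                        f_het_by_genotype = c("WT/WT" = 0.5,
                                              "Cre/WT" = 0.3,
                                              "Cre/Cre" = 0),
                        U_by_genotype = c("WT/WT" = 0.60,
                                          "Cre/Cre" = 0.45),
                        kcng4_fraction = 1, cv = 0.05, U_sd = 0.08,
                        delta_ts_ms = c(10, 20, 50, 100, 200, 500, 1000),
                        train_isis_ms = c(10, 20, 50, 100),
                        n_repeats = 3, n_single = 4,
                        step_amps_pA = NULL, step_duration_ms = 500,
                        step_onset_ms = 100, dt_ms = NULL,
                        noise_sd_pA = NULL) {
  design <- match.arg(design)
  if (is.null(n_cells))
    n_cells <- if (design == "intrinsic")
      c("WT/WT" = 18, "Cre/WT" = 16, "Cre/Cre" = 20)
    else c("WT/WT" = 11, "Cre/Cre" = 10)
  if (any(n_cells < 1)) stop("n_cells must be >= 1 per genotype")
  if (is.null(names(n_cells)) ||
      !all(names(n_cells) %in% c("WT/WT", "Cre/WT", "Cre/Cre")))
    stop("n_cells must be named by genotype")
  if (is.null(step_amps_pA))
    step_amps_pA <- c(seq(-200, 200, by = 40), seq(200, 1200, by = 100))
  if (is.null(dt_ms)) dt_ms <- if (design == "intrinsic") 0.02 else 0.1
  structure(list(design = design, n_cells = n_cells,
                 seed = as.integer(seed),
                 f_het_by_genotype = f_het_by_genotype,
                 U_by_genotype = U_by_genotype,
                 kcng4_fraction = kcng4_fraction, cv = cv, U_sd = U_sd,
                 delta_ts_ms = delta_ts_ms, train_isis_ms = train_isis_ms,
                 n_repeats = n_repeats, n_single = n_single,
                 step_amps_pA = step_amps_pA,
                 step_duration_ms = step_duration_ms,
                 step_onset_ms = step_onset_ms, dt_ms = dt_ms,
                 noise_sd_pA = noise_sd_pA),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws per-cell parameters from the cohort specification and simulates
#' every sweep of the corresponding study design. All randomness flows
#' through R's RNG from `spec$seed`, so repeated calls (and bundles
#' written via `out_dir`) are identical.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory; when given, each cell is also
#'   written as a sweep bundle via [save_cell()].
#' @return A list of [cell_recording()] objects.
#' @examples
#' \donttest{
#' sp <- cohort_spec("synaptic", n_cells = c("WT/WT" = 2, "Cre/Cre" = 2),
#'                   seed = 7)
#' cells <- generate_cohort(sp)
#' }
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cells <- list()
  for (g in names(spec$n_cells)) {
    for (i in seq_len(spec$n_cells[[g]])) {
      id <- sprintf("%s_%s_%02d", spec$design, gsub("/", "", g), i)
      cells[[id]] <- if (spec$design == "intrinsic")
        generate_intrinsic_cell(spec, g, id)
      else generate_synaptic_pair(spec, g, id)
    }
  }
  if (!is.null(out_dir)) {
    for (cl in cells) save_cell(cl, file.path(out_dir, cl$cell_id))
  }
  cells
}

# lognormal-ish between-cell jitter, truncated to stay positive
jitter_cv <- function(x, cv) x * exp(rnorm(1, -cv^2 / 2, cv))

generate_intrinsic_cell <- function(spec, genotype, id) {
  f_het <- spec$f_het_by_genotype[[genotype]]
  if (genotype == "WT/WT" && spec$kcng4_fraction < 1 &&
      stats::runif(1) > spec$kcng4_fraction)
    f_het <- 0
  par <- fs_neuron_params(
    f_het = f_het,
    cm_pF = jitter_cv(90, spec$cv),
    g_leak_nS = jitter_cv(13, spec$cv),
    g_na_nS = jitter_cv(10000, spec$cv),
    g_kv3_nS = jitter_cv(1400, spec$cv),
    g_kv2_nS = jitter_cv(1000, spec$cv),
    noise_sd_pA = if (is.null(spec$noise_sd_pA)) 20 else spec$noise_sd_pA)
  sweeps <- vector("list", length(spec$step_amps_pA))
  for (k in seq_along(spec$step_amps_pA)) {
    pr <- step_protocol(spec$step_amps_pA[k], spec$step_onset_ms,
                        spec$step_duration_ms)
    sweeps[[k]] <- simulate_fs_neuron(par, pr, dt_ms = spec$dt_ms,
                                      sweep_id = sprintf("step_%02d", k))
  }
  rs <- jitter_cv(11, 0.1)
  cell_recording(id, genotype, sweeps,
                 passive = passive_props(R_series_MOhm = rs,
                                         R_membrane_MOhm = 1000 /
                                           par[["g_leak_nS"]],
                                         V_rest_mV = -74.6,
                                         holding_current_pA = 0))
}

generate_synaptic_pair <- function(spec, genotype, id) {
  if (!genotype %in% names(spec$U_by_genotype))
    stop("no release probability configured for genotype ", genotype)
  U <- rnorm(1, spec$U_by_genotype[[genotype]], spec$U_sd)
  U <- min(0.95, max(0.05, U))
  rs <- if (genotype == "WT/WT") 18.93 else 20.40
  rm <- if (genotype == "WT/WT") 210.90 else 204.11
  rs <- jitter_cv(rs, 0.08)
  rm <- jitter_cv(rm, 0.08)
  par <- synapse_params(
    U = U, scale_pA = jitter_cv(2000, spec$cv),
    R_series_MOhm = rs, R_membrane_MOhm = rm,
    noise_sd_pA = if (is.null(spec$noise_sd_pA)) 20 else spec$noise_sd_pA)

  sweeps <- list()
  tp <- simulate_test_pulse(R_series_MOhm = rs, R_membrane_MOhm = rm,
                            C_m_pF = 150, holding_pA = par$holding_pA,
                            noise_sd_pA = 2)
  tp_meta <- attr(tp, "test_pulse")
  sweeps[[tp$sweep_id]] <- tp
  k <- 0L
  add <- function(stim, tag) {
    k <<- k + 1L
    sw <- simulate_ipsc_train(par, stim, dt_ms = spec$dt_ms,
                              sweep_id = sprintf("%s_%03d", tag, k))
    sweeps[[sw$sweep_id]] <<- sw
  }
  for (r in seq_len(spec$n_single))
    add(stim_train(50), "single")
  for (d in spec$delta_ts_ms) for (r in seq_len(spec$n_repeats))
    add(stim_train(c(50, 50 + d)), sprintf("pp%04d", d))
  for (d in spec$train_isis_ms) for (r in seq_len(spec$n_repeats))
    add(stim_train(50 + d * (0:4)), sprintf("tr%04d", d))

  cell <- cell_recording(id, genotype, sweeps,
                         passive = passive_props(
                           R_series_MOhm = rs, R_membrane_MOhm = rm,
                           holding_current_pA = par$holding_pA))
  attr(cell, "test_pulse_meta") <- tp_meta
  attr(cell, "true_U") <- U
  cell
}
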