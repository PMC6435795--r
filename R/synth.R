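#' Generate a labelled synthetic multi-program virtual screen
#'
#' Emulates the statistical structure of a docking-based virtual screen
#' without running any docking engine. Every molecule carries a latent "true
#' affinity" `a_i = mu * 1[ligand] + N(0, latent_sd^2)` shared across
#' programs; program j reports
#'
#'   `s_ij = offset_j + scale_j * (-quality_j * a_i - (1 - quality_j) * e_ij)`
#'
#' where `e_ij = sqrt(rho) * c_i + sqrt(1 - rho) * eta_ij` mixes a common
#' noise channel `c_i` (inter-program correlation `rho`) with program-private
#' noise. A program with `quality = 0` reproduces the random scoring function
#' statistically (pure noise, expected ROC-AUC 0.5 — a "broken" engine);
#' `quality = 1` with all noise off reports the latent affinity exactly.
#' Offsets and scales mimic the program-specific units of real docking
#' scores: they change raw scores but leave every program's *ranking* — and
#' hence all rank-based consensus strategies — untouched.
#'
#' The defaults describe the reference benchmark condition used throughout
#' the package's tests: 2000 molecules, 10% ligands, six programs of graded
#' quality including one broken program, moderate inter-program correlation.
#' The default `mu` is calibrated analytically so a quality-0.8 program
#' attains ROC-AUC of about 0.8
#' (`AUC = pnorm(q * mu / sqrt(2 * (q^2 * latent_sd^2 + (1 - q)^2)))`).
#'
#' @param n_molecules Number of molecules.
#' @param ligand_fraction Fraction of molecules labelled `ligand` (rounded to
#'   a count; must leave at least one ligand and one decoy).
#' @param n_programs Number of simulated docking programs.
#' @param program_quality Numeric vector (length `n_programs`) in \[0, 1\]:
#'   per-program signal weight; 0 = broken/random program.
#' @param correlation Inter-program noise correlation `rho` in \[0, 1\].
#' @param offset,scale Per-program score offset and (positive) scale.
#' @param mu Latent affinity separation between ligands and decoys.
#' @param latent_sd Standard deviation of the latent affinity noise (0 makes
#'   the latent signal deterministic).
#' @param seed Integer seed; identical seeds give identical screens.
#' @return A list with elements `scores` (long tibble: `molecule_id`,
#'   `program`, `score`, `direction = "lower"`), `labels` (tibble:
#'   `molecule_id`, `label`) and `config` (the resolved parameters).
#' @export
#' @examples
#' screen <- synthetic_screen(n_molecules = 200, seed = 7)
#' dplyr::count(screen$labels, label)
synthetic_screen <- function(n_molecules = 2000,
                             ligand_fraction = 0.1,
                             n_programs = 6,
                             program_quality = c(0.8, 0.7, 0.6, 0.5, 0.4, 0),
                             correlation = 0.3,
                             offset = rep(0, n_programs),
                             scale = rep(1, n_programs),
                             mu = 1.227,
                             latent_sd = 1,
                             seed) {
  if (length(program_quality) != n_programs ||
      length(offset) != n_programs || length(scale) != n_programs) {
    abort("program_quality, offset and scale must have length n_programs")
  }
  if (any(program_quality < 0 | program_quality > 1)) {
    abort("program_quality must lie in [0, 1]")
  }
  if (any(scale <= 0)) abort("scales must be positive")
  if (correlation < 0 || correlation > 1) abort("correlation must lie in [0, 1]")
  n_lig <- round(ligand_fraction * n_molecules)
  if (n_lig < 1 || n_lig >= n_molecules) {
    abort("ligand_fraction leaves no ligands or no decoys")
  }
  width <- nchar(as.character(n_molecules))
  ids <- sprintf(paste0("M%0", width, "d"), seq_len(n_molecules))

  dat <- withr::with_seed(seed, {
    is_lig <- logical(n_molecules)
    is_lig[sample.int(n_molecules, n_lig)] <- TRUE
    a <- mu * is_lig + rnorm(n_molecules, sd = latent_sd)
    common <- rnorm(n_molecules)
    scores <- purrr::map(seq_len(n_programs), function(j) {
      q <- program_quality[j]
      eta <- rnorm(n_molecules)
      e <- sqrt(correlation) * common + sqrt(1 - correlation) * eta
      tibble::tibble(
        molecule_id = ids,
        program = sprintf("prog%d", j),
        score = offset[j] + scale[j] * (-q * a - (1 - q) * e),
        direction = "lower"
      )
    }) |> purrr::list_rbind()
    list(scores = scores, is_lig = is_lig)
  })

  labels <- tibble::tibble(
    molecule_id = ids,
    label = ifelse(dat$is_lig, "ligand", "decoy")
  )
  config <- list(n_molecules = n_molecules, ligand_fraction = ligand_fraction,
                 n_programs = n_programs, program_quality = program_quality,
                 correlation = correlation, offset = offset, scale = scale,
                 mu = mu, latent_sd = latent_sd, seed = seed)
  list(scores = assert_scores(dat$scores), labels = labels, config = config)
}
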