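# Small constructors for fixtures built in code.

# scores: named list program -> named numeric vector (names = molecule ids)
make_scores <- function(..., direction = "lower") {
  programs <- list(...)
  purrr::imap(programs, function(v, p) {
    tibble::tibble(molecule_id = names(v), program = p,
                   score = unname(v), direction = direction)
  }) |> purrr::list_rbind()
}

# ranks: named list program -> named integer rank vector
make_ranks <- function(...) {
  programs <- list(...)
  purrr::imap(programs, function(v, p) {
    tibble::tibble(molecule_id = names(v), program = p, rank = as.integer(v))
  }) |> purrr::list_rbind()
}

make_labels <- function(ligands, decoys) {
  tibble::tibble(molecule_id = c(ligands, decoys),
                 label = rep(c("ligand", "decoy"),
                             c(length(ligands), length(decoys))))
}

# a strict ranking tibble from an ordered id vector (first = best)
make_ranking <- function(ids_in_order) {
  tibble::tibble(molecule_id = ids_in_order,
                 rank = seq_along(ids_in_order))
}

write_score_csv <- function(ids, scores, path = tempfile(fileext = ".csv")) {
  readr::write_csv(tibble::tibble(molecule_id = ids, score = scores), path)
  path
}

# random small instance for oracle-equivalence checks
random_instance <- function(n_mol, n_prog, seed) {
  withr::with_seed(seed, {
    ids <- sample(LETTERS, n_mol)
    scores <- lapply(seq_len(n_prog), function(j) {
      stats::setNames(round(stats::rnorm(n_mol), 2), ids)
    })
    names(scores) <- paste0("p", seq_len(n_prog))
    scores
  })
}
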