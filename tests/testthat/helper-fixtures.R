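# Shared fixtures, built in code at test time.

# Small channel set for hand-computed cases.
toy_channels <- function(n = 3) {
  labs <- LETTERS[seq_len(n)]
  groups <- stats::setNames(rep(c("1x", "2x"), length.out = n), labs)
  channel_set(labs, groups)
}

# Assemble a psm_table from an intensity matrix and optional metrics.
toy_table <- function(m, channels = NULL, species = "human",
                      sequence = NULL, master = NULL,
                      delta_cn = 1, coisolation = 0, avg_sn = Inf) {
  n <- nrow(m)
  channels <- channels %||% toy_channels(ncol(m))
  colnames(m) <- channels$labels
  psms <- tibble::tibble(
    psm_id = sprintf("P%03d", seq_len(n)),
    sequence = sequence %||% sprintf("SEQ%03d", seq_len(n)),
    master_proteins = master %||% sprintf("PROT%03d", seq_len(n)),
    species = rep_len(species, n),
    delta_cn = rep_len(delta_cn, n),
    coisolation_pct = rep_len(coisolation, n),
    avg_sn = rep_len(avg_sn, n)
  )
  psm_table(dplyr::bind_cols(psms, tibble::as_tibble(m)), channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One reference benchmark simulation per parameter signature, cached across
# test files (simulations are deterministic in the seed).
.sim_cache <- new.env(parent = emptyenv())

ref_sim <- function(seed = 1234, ...) {
  key <- paste(deparse(list(seed = seed, ...)), collapse = "")
  key <- digest_key(key)
  if (is.null(.sim_cache[[key]])) {
    design <- build_mix_design()
    .sim_cache[[key]] <- simulate_experiment(design,
                                             sim_params(seed = seed, ...))
  }
  .sim_cache[[key]]
}

digest_key <- function(s) paste0("k", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))))

# Replace the intensity block of a psm_table (tests only).
set_intensities_for_test <- function(x, m) {
  x$psms[, x$channels$labels] <- tibble::as_tibble(m, .name_repair = "minimal")
  x
}
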