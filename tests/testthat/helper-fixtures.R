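# Shared fixtures: tiny hierarchies, configurations, toy PSSM writer, and
# a cache so expensive trained objects are built once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

toy_hierarchy <- function() {
  hierarchy(list(alpha = c("a1", "a2"), beta = "b1", gamma = "g1"))
}

tiny_config <- function(n_org = 3, seed = 7L, ...) {
  loc_config(n_org = n_org, hidden = 4, attn_inner = 6, heads = 3,
             encode_len = 40, seed = seed, ...)
}

random_sequence <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(c("M", sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                      n - 1, replace = TRUE)), collapse = "")
}

# Writes a minimal PSI-BLAST ASCII PSSM for the given log-odds matrix.
write_toy_pssm <- function(scores, residues, path) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  lines <- c("",
             "Last position-specific scoring matrix computed, weighted, observed",
             paste0("      ", paste(aa, collapse = "   "), "   ",
                    paste(aa, collapse = "   ")))
  for (i in seq_len(nrow(scores))) {
    lines <- c(lines, paste0(sprintf("%5d %s ", i, residues[i]),
                             paste(sprintf("%3d", scores[i, ]), collapse = " "),
                             " ", paste(rep("  0", 20), collapse = " ")))
  }
  lines <- c(lines, "", "                      K         Lambda")
  writeLines(lines, path)
  path
}

# A small untrained model over the toy hierarchy (mechanics tests only).
toy_model <- function(seed = 7L) {
  cached(paste0("toy_model_", seed), {
    cfg <- tiny_config(seed = seed)
    structure(list(params = attnloc:::init_params(cfg), cfg = cfg,
                   cycles = 0L, hierarchy = toy_hierarchy(),
                   log = tibble::tibble(alternation = integer(0),
                                        phase = character(0),
                                        mean_loss = numeric(0))),
              class = "loc_model")
  })
}

toy_records <- function(n_per_class = 5, seed = 3L, len = c(45, 60)) {
  set.seed(seed)
  h <- toy_hierarchy()
  rows <- list()
  i <- 0
  for (cl in seq_len(nrow(h$cells))) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1
      rows[[i]] <- protein_record(
        sprintf("T%03d", i), random_sequence(sample(len[1]:len[2], 1)),
        organelles = h$cells$organelle[cl],
        suborganelles = h$cells$suborganelle[cl],
        created_year = sample(2010:2022, 1))
    }
  }
  dplyr::bind_rows(rows)
}

# The desk-scale recovery experiment, run once and shared by the
# acceptance blocks.
get_recovery <- function() {
  cached("recovery", recovery_experiment(seed = 101L))
}
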