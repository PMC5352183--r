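# Small in-code fixtures shared across tests.

toy_mutation_table <- function() {
  universe <- tibble::tibble(
    cancer_type = "TT",
    sample_id = sprintf("S%02d", 1:10))
  records <- tibble::tibble(
    sample_id = c("S01", "S02", "S03", "S04", "S05"),
    cancer_type = "TT",
    gene_symbol = c("TP53", "TP53", "TP53", "TP53", "GENEB"),
    variant_class = c("missense", "nonsense", "silent",
                      "frame_shift_del", "missense"))
  mutation_table(records, universe)
}

# A deterministic two-group study: `n_a` samples in group a ("mutated"),
# `n_b` in group b ("wildtype"), `n_n` normals; `shift` added to group a
# for the first `n_shift` genes.
toy_study <- function(genes = 20, n_a = 12, n_b = 12, n_n = 6,
                      shift = 2, n_shift = 5, sigma = 0.5, seed = 42) {
  withr::with_seed(seed, {
    ids_a <- sprintf("A%02d", seq_len(n_a))
    ids_b <- sprintf("B%02d", seq_len(n_b))
    ids_n <- sprintf("N%02d", seq_len(n_n))
    samples <- c(ids_a, ids_b, ids_n)
    gene_ids <- c("TP53", sprintf("G%03d", seq_len(genes - 1)))
    m <- matrix(rnorm(genes * length(samples), mean = 8, sd = sigma),
                nrow = genes, dimnames = list(gene_ids, samples))
    if (n_shift > 0) {
      m[seq_len(n_shift) + 1, ids_a] <- m[seq_len(n_shift) + 1, ids_a] +
        shift
    }
    meta <- tibble::tibble(
      sample_id = samples,
      tissue = rep(c("tumor", "tumor", "normal"), c(n_a, n_b, n_n)),
      tp53_group = rep(c("non_truncating", "wildtype", "not_applicable"),
                       c(n_a, n_b, n_n)))
    expression_study("TT", m, meta)
  })
}

lenient_config <- function(...) {
  run_config(min_group = 2, min_normals = 2, ...)
}
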