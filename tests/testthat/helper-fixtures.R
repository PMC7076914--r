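# Shared fixtures, built in code. Sizes are kept small: these exist to
# exercise contracts, not to benchmark.

default_grid <- c(0, 5, 10, 15, 20, 30, 45, 90)

# a tiny three-gene cascade A -> B -> D (plus a bystander C), with strong
# coefficients so every stage of the pipeline sees clean signal
make_cascade_network <- function(a_ba = 8e-4, a_db = 1.2e-3) {
  net <- generate_network(4, 3, sparsity = 1e-9, seed = 1)
  net$gene_ids <- c("gA", "gB", "gC", "gD")
  dimnames(net$alpha) <- list(net$gene_ids, net$gene_ids)
  dimnames(net$beta) <- dimnames(net$alpha)
  net$regulators <- c("gA", "gB", "gC")
  net$alpha["gB", "gA"] <- a_ba   # A induces B
  net$alpha["gD", "gB"] <- a_db   # B induces D
  net
}

cascade_designs <- function() {
  list(induction_design("expA", "gA"),
       induction_design("expB", "gB"),
       induction_design("expC", "gC"))
}

# mid-scale recovery benchmark shared by netmodel tests
make_benchmark <- function(n_genes = 50, n_regulators = 10, n_exp = 20,
                           sparsity = 0.02, noise_log2 = 0.1,
                           seed = 101) {
  net <- generate_network(n_genes, n_regulators, sparsity, seed = seed)
  designs <- lapply(seq_len(n_exp), function(j) {
    induction_design(paste0("e", j),
                     net$regulators[(j - 1) %% n_regulators + 1],
                     system_class = if (j %% 2) "ZEV" else "GEV")
  })
  cube <- simulate_experiments(net, designs)
  obs <- corrupt_with_noise(
    cube, noise_spec(gene_log_sd = noise_log2 * log(2), array_log_sd = 0,
                     seed = seed + 1))
  truth <- which(net$alpha != 0 | net$beta != 0, arr.ind = TRUE)
  list(net = net, designs = designs, cube = cube, obs = obs,
       true_edges = data.frame(
         a = colnames(net$alpha)[truth[, 2]],
         b = rownames(net$alpha)[truth[, 1]], stringsAsFactors = FALSE))
}
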