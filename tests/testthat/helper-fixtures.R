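# small clustered UMI fixture with controllable boundary cells
cat_fixture <- function(seed = 90, n_per = 40, fold = 8) {
  set.seed(seed)
  genes <- c(paste0("MT-", 1:3), sprintf("g%03d", 1:97))
  cells <- sprintf("c%03d", seq_len(3 * n_per))
  lab <- rep(c("k1", "k2", "k3"), each = n_per)
  mu <- matrix(30, length(cells), length(genes),
               dimnames = list(cells, genes))
  mu[lab == "k1", 4:13] <- 30 * fold
  mu[lab == "k2", 14:23] <- 30 * fold
  mu[lab == "k3", 24:33] <- 30 * fold
  umis <- matrix(rnbinom(length(mu), mu = mu, size = 5), nrow(mu),
                 dimnames = dimnames(mu))
  cell_matrix(umis, tibble::tibble(cell = cells, cluster = lab))
}
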