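# random small instances with explicit cost matrices, for property tests
random_instance <- function(seed, n_div = 5, n_comm = 4, n_tert = 2,
                            rho = 0.4) {
  set.seed(seed)
  div <- data.frame(
    id = sprintf("k%d", seq_len(n_div)),
    x = runif(n_div, 0, 10), y = runif(n_div, 0, 10),
    pop_total = round(runif(n_div, 2000, 50000)),
    pop_elderly = round(runif(n_div, 500, 20000)),
    pop_chronic = round(runif(n_div, 100, 8000)))
  sit <- data.frame(
    id = c(sprintf("c%d", seq_len(n_comm)), sprintf("t%d", seq_len(n_tert))),
    tier = c(rep("community", n_comm), rep("tertiary_A", n_tert)),
    x = runif(n_comm + n_tert, 0, 10), y = runif(n_comm + n_tert, 0, 10),
    resource_offline = round(runif(n_comm + n_tert, 50, 500)),
    online_cap_fraction = c(rep(0, n_comm), rep(rho, n_tert)))
  th_instance(div, sit)
}

baseline_fit <- function(instance, ...) {
  zQ <- stats::setNames(rep(0, nrow(instance$divisions)),
                        instance$divisions$id)
  i2sfca(instance, Q = zQ, ...)
}
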