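# brute-force per-edge/per-vertex index evaluation straight from the graph,
# independent of the class-wise partition path it is used to check
brute_force_indices <- function(g) {
  d <- g$degrees
  ds <- as.numeric(d[g$edges[, 1L]])
  dt <- as.numeric(d[g$edges[, 2L]])
  list(
    abc_r = sum((sqrt(ds + dt - 2) - 1) / sqrt(ds * dt)),
    ga = sum(2 * sqrt(ds * dt) / (ds + dt)),
    sdd = sum((ds^2 + dt^2) / (ds * dt)),
    ln_epi1 = sum(as.integer(d)^2),
    ln_epi2 = sum(as.integer(ds) * as.integer(dt)),
    ga_pi_edgewise = prod(2 * sqrt(ds * dt) / (ds + dt)))
}

make_k2 <- function() molecular_graph(c("a", "b"))

path_graph <- function(n) {
  v <- paste0("p", seq_len(n))
  molecular_graph(cbind(v[-n], v[-1L]))
}

cycle_graph <- function(n) {
  v <- paste0("c", seq_len(n))
  molecular_graph(rbind(cbind(v[-n], v[-1L]), c(v[n], v[1L])))
}

# the tabulated thalidomide edge partition, passed as plain data
thalidomide_partition <- function() {
  data.frame(d1 = c(1, 2, 2, 3), d2 = c(3, 2, 3, 3), freq = c(4, 4, 6, 7))
}

random_permutation <- function(g) {
  new <- sample(paste0("w", seq_along(g$vertices)))
  names(new) <- g$vertices
  new
}
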