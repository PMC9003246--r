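# shared fixtures for the test suite (built in code, no external files)

liver <- liver_params()

rel_err <- function(x, ref) abs(x - ref) / pmax(abs(ref), .Machine$double.xmin)

# two-node, one-element mesh for exact single-spring checks
single_element_mesh <- function(L = 0.01) {
  spring_mesh(rbind(c(0, 0, 0), c(L, 0, 0)), rbind(c(1L, 2L)),
              fixed_nodes = 1L, driven_nodes = 2L)
}

# independent re-evaluation of the isotropic energy, written out long-hand
w_iso_reference <- function(lam, mu, N) {
  bracket <- function(l) {
    lr <- sqrt((l^2 + 2 / l) / (3 * N))
    beta <- 3 * lr / (1 - lr^3)
    mu * (N * (beta * lr + log(beta / sinh(beta))) - log(beta * lr))
  }
  bracket(lam) - bracket(1)
}
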