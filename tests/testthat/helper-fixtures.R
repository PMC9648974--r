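# Shared fixture builders. Everything is generated in code; no stored data.

uniform_phantom <- function(n = 8, t1 = 800, t2star = 20, f = 0,
                            noise_sd = 0, seed = 1) {
  phantom_spec(c(n, n), t1_field = t1, t2star_field = t2star,
               perfusion_field = f, proton_density = 1000,
               noise_sd = noise_sd, seed = seed)
}

# Independent forward convolution oracle for the correction matrix: builds
# the observed MID of a pure m+j species by explicit polynomial
# multiplication over every atom, one atom at a time.
oracle_observed_mid <- function(frag, iso, j, size) {
  poly <- 1
  mult <- function(p, q) {
    out <- numeric(length(p) + length(q) - 1L)
    for (i in seq_along(p)) for (k in seq_along(q))
      out[i + k - 1L] <- out[i + k - 1L] + p[i] * q[k]
    out
  }
  for (el in names(frag$element_counts)) {
    n_at <- frag$element_counts[[el]] - if (el == "C") j else 0L
    if (n_at > 0) for (a in seq_len(n_at)) poly <- mult(poly, iso[[el]])
  }
  full <- numeric(size)
  take <- seq_len(min(length(poly), size - j))
  full[j + take] <- poly[take]
  full / sum(full)
}

tiny_abundance <- function(values, scale = "raw") {
  abundance_table(values, scale = scale)
}
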