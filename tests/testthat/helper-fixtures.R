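# shared helpers: tiny hand-built species and states

default_params <- model_params()

# a species with the given traits/bodysize, non-resource by default
sp <- function(traits, bodysize = 1, is_resource = FALSE) {
  species(traits, bodysize, is_resource = is_resource)
}

# a score matrix with a hand-set trait-pair block: every (i-trait, j-trait)
# pair scores `value`, so the pair sum of a 10-trait consumer on a 10-trait
# prey is 100 * value
block_beta <- function(pool, i_traits, j_traits, value) {
  beta <- matrix(0, pool, pool)
  beta[i_traits, j_traits] <- value
  beta[j_traits, i_traits] <- -value
  beta
}

# scalar fixed-point oracle for one consumer on one prey (f = 1 throughout):
# iterate g = S * Np / (sat * Np + alpha * S * g-weighted consumer pop)
scalar_forage_oracle <- function(S, alpha, Nc, Np, sat, iters = 200) {
  g <- 0
  for (k in seq_len(iters)) g <- S * Np / (sat * Np + alpha * S * Nc)
  g
}

# straight-line transcription of the allometric Euler update for one patch:
# N_i += Delta * (-2 s_i^-0.25 N_i + lambda/s_i N_i sum_j g_ij s_j
#                 - sum_k N_k g_ki)
euler_oracle <- function(N, s, is_res, g, params) {
  out <- N
  for (i in seq_along(N)) {
    if (is_res[i]) next
    gain <- 0
    for (j in seq_along(N)) gain <- gain + g[i, j] * s[j]
    pred <- 0
    for (k in seq_along(N)) pred <- pred + N[k] * g[k, i]
    out[i] <- max(0, N[i] + params$delta_t *
                    (-2 * s[i]^(-0.25) * N[i] +
                       params$lambda_eff * N[i] * gain / s[i] - pred))
  }
  out
}
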