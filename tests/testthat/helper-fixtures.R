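# shared fixtures built in code

# plateau-decay |S_CD| template for a perdeuterated palmitoyl sn-1
# chain (carbons 2..16): flat plateau over the upper chain, smooth
# decay to the terminal methyl. Scaled so its unweighted mean equals
# `mean_s`.
template_profile <- function(mean_s, n_c = 16) {
  carb <- 2:n_c
  shape <- ifelse(carb <= 8, 1, cos((carb - 8) / (n_c - 8) * pi / 2) * 0.75 + 0.25)
  order_profile(carb, shape * mean_s / mean(shape))
}

# leakage kinetics reference triples (k 1/min, a0 %, tc min) for
# PC/PG-cholesterol vesicle systems exposed to 0.6 mM imidazolium IL
ref_kinetics <- list(
  pc_chol_10_0 = c(k = 0.52, a0 = 99.1, tc = 0.87),
  pg_chol_9_1  = c(k = 0.30, a0 = 57.75, tc = 8.20),
  pg_chol_8_2  = c(k = 0.20, a0 = 41.42, tc = 20.60)
)

# noiseless leakage round trip: generate -> normalize -> (optionally) fit
make_leakage <- function(p, t_end = 40, dt = 0.1) {
  spec <- leakage_trace_spec(a0 = p[["a0"]], k = p[["k"]], tc = p[["tc"]],
                             t_end = t_end, dt = dt)
  tr <- gen_leakage_traces(spec)
  normalize_leakage(tr$sample, tr$baseline, tr$triton)
}

# pure-component isotherms sampled on a shared pressure grid, so that
# mole-fraction-weighted ideality cancels exactly on the grid knots
pure_on_grid <- function(spec_a, spec_b, which = c("a", "b"), ...) {
  which <- match.arg(which)
  chi <- if (which == "a") c(1, 0) else c(0, 1)
  gen_mixed_isotherm(spec_a, spec_b,
                     mixture_composition(c("a", "b"), chi), ...)
}
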