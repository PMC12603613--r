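# shared fixtures: small deterministic stacks and tables built in code

hb_tab <- hb_extinction()

# mid-range three-layer stack, depth-20 preset geometry
stack3 <- function(fetal_sao2 = 0.5, depth = 20) {
  thk1 <- if (depth == 20) 5 else 20
  tissue_stack(list(
    optical_layer(thk1, 40, 0.95, 1.2, 1.0),
    optical_layer(15, 60, 0.95, 1.0, 1.0),
    optical_layer(Inf, 80, fetal_sao2, 0.6, 1.0)
  ))
}

# two-layer sheep-style stack (15 mm maternal over semi-infinite fetal)
stack2 <- function(fetal_sao2 = 0.5) {
  tissue_stack(list(
    optical_layer(15, 55, 0.98, 1.1, 1.0),
    optical_layer(Inf, 95, fetal_sao2, 0.4, 1.0)
  ), wavelengths = c(756, 785, 812, 825, 846, 855))
}

tiny_cohort <- function(n = 5, depth = 20, seed = 42)
  cohort_config(n_subjects = n, fetal_depth = depth, seed = seed)
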