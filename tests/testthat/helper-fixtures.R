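# shared fixtures: hand-built posteriors and small sampler settings

# a bart_fit wrapping hand-specified forests, for exact-evaluation tests.
# each tree is a matrix with columns (var 0-based | -1 for leaf, cut/mask,
# left, right, value); states is a list of forests (lists of such matrices).
hand_fit <- function(states, schema, center = 0, range = 1) {
  structure(list(states = states, sigma = rep(1, length(states)),
                 center = center, range = range, schema = schema,
                 config = bart_config(n_draws = max(1, length(states))),
                 n_states = length(states), constant = NULL,
                 accept_rates = c(grow = NA, prune = NA, change = NA)),
            class = "bart_fit")
}

leaf_node <- function(value) c(-1, 0, -1, -1, value)

# single split on continuous variable `var0` (0-based) at `cut`:
# x <= cut -> value_left, else value_right
stump_continuous <- function(var0, cut, value_left, value_right) {
  rbind(c(var0, cut, 1, 2, 0), leaf_node(value_left), leaf_node(value_right))
}

# single split on a two-level factor coded (0, 1): level code 0 goes left
stump_binary_factor <- function(var0, value_level1, value_level2) {
  rbind(c(var0, 1, 1, 2, 0),  # mask 1 = bit 0 set = first level left
        leaf_node(value_level1), leaf_node(value_level2))
}

tiny_bart <- function(...) bart_config(n_trees = 10, n_burn = 100,
                                       n_draws = 200, ...)

# small complete cohort with treatments discretized, ready for bart()
model_frame <- function(cohort) {
  dat <- rehabite:::discretize_treatments(cohort)
  as.data.frame(dat[, predictor_names()])
}
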