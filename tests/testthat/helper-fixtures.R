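# Shared test fixtures, built in code.

# Deterministic tiny two-dimension bank (not randomly generated, so tests
# can reason about individual items).
make_handmade_bank <- function() {
  item_bank(data.frame(
    item_id = 1:8,
    dimension = c(1, 1, 1, 1, 2, 2, 2, 2),
    a = c(1.0, 1.2, 0.8, 1.5, 1.1, 0.9, 1.3, 1.0),
    b = c(0.0, -0.5, 0.6, 0.1, 0.0, 0.4, -0.3, 1.0),
    c = c(0.0, 0.10, 0.20, 0.05, 0.0, 0.15, 0.25, 0.10)
  ))
}

# Random small bank via the generator.
make_tiny_bank <- function(seed = 101, items_per_dim = 20L) {
  set.seed(seed)
  generate_bank(items_per_dim, D = 2L)
}

# Random response set referencing a bank.
make_random_responses <- function(bank, k = 6L) {
  idx <- sample(nrow(bank), k)
  data.frame(item_id = bank$item_id[idx],
             u = sample(0:1, k, replace = TRUE))
}

default_spec <- function(cutoffs = c(0, 0)) classification_spec(cutoffs)
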