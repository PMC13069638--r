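# Small circuits reused across the suite; all built in code.

decay_node <- function(d = 0.1) {
  circuit(data.frame(name = "X", total = 1, d = d, basal = 0),
          data.frame(source = character(), target = character(),
                     sign = numeric(), k = numeric(), j = numeric(),
                     n = numeric()),
          input = "X", output = "X", s = 0)
}

# single node under a saturated constant activator (phi ~ 1)
activated_node <- function(k = 1, d = 1) {
  circuit(data.frame(name = "X", total = 1, d = d, basal = 0),
          data.frame(source = ".stim", target = "X", sign = 1, k = k,
                     j = 1e-6, n = 1),
          input = "X", output = "X", s = 1)
}

# random stable-ish circuit generator for property tests
random_circuit <- function(n_nodes = 3, seed = 1) {
  set.seed(seed)
  nodes <- data.frame(name = LETTERS[seq_len(n_nodes)],
                      total = runif(n_nodes, 0.3, 1),
                      d = runif(n_nodes, 0.05, 0.5),
                      basal = 0.01)
  pairs <- expand.grid(source = nodes$name, target = nodes$name,
                       stringsAsFactors = FALSE)
  keep <- runif(nrow(pairs)) < 0.6
  pairs <- pairs[keep, , drop = FALSE]
  edges <- rbind(
    data.frame(source = ".stim", target = "A", sign = 1,
               k = runif(1, 0.3, 3), j = runif(1, 0.1, 1),
               n = sample(1:4, 1)),
    if (nrow(pairs))
      data.frame(source = pairs$source, target = pairs$target,
                 sign = sample(c(-1, 1), nrow(pairs), replace = TRUE),
                 k = runif(nrow(pairs), 0.1, 5),
                 j = runif(nrow(pairs), 0.01, 2),
                 n = sample(1:4, nrow(pairs), replace = TRUE)))
  circuit(nodes, edges, input = "A", output = nodes$name[n_nodes],
          s = runif(1))
}

# four-parameter logistic, written out independently for fit-recovery checks
fpl_fun_test <- function(x, p)
  p$A + (p$B - p$A) / (1 + exp((p$xmid - x) / p$scal))
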