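# Shared fixtures: small models and an independent loop-enumeration oracle.

decay_model <- function(k = 0.1, s0 = 100, horizon = list(start = 0, end = 10, dt = 1)) {
  sd_model("decay", horizon = horizon,
           stocks = list(sd_stock("S", s0)),
           flows = list(sd_flow("outflow", "k * S", source = "S",
                                signs = c(S = 1))),
           parameters = list(k = k))
}

two_stock_model <- function(horizon = list(start = 0, end = 20, dt = 1)) {
  sd_model("transfer", horizon = horizon,
           stocks = list(sd_stock("A", 80), sd_stock("B", 20)),
           flows = list(sd_flow("drain", "0.05 * A", source = "A", sink = "B",
                                signs = c(A = 1))))
}

# closed form of the explicit Euler recurrence for dS/dt = -kS
euler_decay_closed_form <- function(s0, k, dt, n) s0 * (1 - k * dt)^n

random_signed_graph <- function(n_nodes, p_link = 0.35) {
  nodes <- paste0("n", seq_len(n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p_link
  links <- pairs[keep, , drop = FALSE]
  links$sign <- sample(c(-1, 1), nrow(links), replace = TRUE)
  causal_graph(nodes, links)
}

# independent oracle: exhaustive simple-path search with closure check; a
# cycle is collected only from its lexicographically smallest node, so each
# elementary circuit appears exactly once in canonical form
brute_force_loops <- function(graph) {
  nodes <- sort(graph$nodes)
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    sort(graph$links$target[graph$links$source == v]))
  out <- list()
  dfs <- function(start, v, path) {
    for (w in adj[[v]]) {
      if (w == start) {
        out[[length(out) + 1L]] <<- path
      } else if (w > start && !(w %in% path)) {
        dfs(start, w, c(path, w))
      }
    }
  }
  for (s in nodes) dfs(s, s, s)
  keys <- vapply(out, paste, character(1), collapse = "\x1f")
  out[order(keys)]
}

loop_key <- function(l) paste(l$cycle, collapse = "\x1f")

link_sign_of <- function(g, from, to) {
  i <- which(g$links$source == from & g$links$target == to)
  if (length(i) == 0L) NA_real_ else g$links$sign[[i]]
}
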