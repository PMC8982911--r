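# Causal-loop analysis: enumeration, polarity, audit, extraction.

test_that("elementary circuits are enumerated exactly once in canonical form", {
  g <- causal_graph(c("A", "B"),
                    data.frame(source = c("A", "B"), target = c("B", "A"),
                               sign = c(1, 1)))
  loops <- enumerate_loops(g)
  expect_length(loops, 1L)
  expect_identical(loops[[1L]]$cycle, c("A", "B"))

  # complete digraph on 3 nodes: three 2-cycles and two 3-cycles
  nodes <- c("A", "B", "C")
  pairs <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs$sign <- 1
  loops <- enumerate_loops(causal_graph(nodes, pairs))
  expect_length(loops, 5L)
  expect_identical(sort(vapply(loops, `[[`, integer(1), "length")),
                   c(2L, 2L, 2L, 3L, 3L))
})

test_that("enumeration agrees with the brute-force oracle on random digraphs", {
  set.seed(42)
  for (rep in 1:25) {
    g <- random_signed_graph(sample(3:8, 1L))
    mine <- lapply(enumerate_loops(g), `[[`, "cycle")
    oracle <- brute_force_loops(g)
    expect_identical(mine, oracle)
  }
})

test_that("loop count is invariant under node relabeling", {
  set.seed(7)
  g <- random_signed_graph(6)
  relabel <- stats::setNames(paste0("z", rev(seq_along(g$nodes))), g$nodes)
  g2 <- causal_graph(unname(relabel[g$nodes]),
                     data.frame(source = unname(relabel[g$links$source]),
                                target = unname(relabel[g$links$target]),
                                sign = g$links$sign))
  expect_identical(length(enumerate_loops(g)), length(enumerate_loops(g2)))
})

test_that("polarity is the sign product, rotation-invariant, and flips with one link", {
  nodes <- c("A", "B", "C")
  links <- data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
                      sign = c(1, 1, 1))
  g <- causal_graph(nodes, links)
  expect_identical(loop_polarity(c("A", "B", "C"), g), "reinforcing")
  expect_identical(loop_polarity(c("B", "C", "A"), g), "reinforcing")
  expect_identical(loop_polarity(c("C", "A", "B"), g), "reinforcing")
  links$sign[2L] <- -1
  g2 <- causal_graph(nodes, links)
  expect_identical(loop_polarity(c("A", "B", "C"), g2), "balancing")
  expect_error(loop_polarity(c("A", "C"), g), "A -> C")
})

test_that("graph construction rejects self-links, duplicates and unknown endpoints", {
  expect_error(causal_graph("A", data.frame(source = "A", target = "A", sign = 1)),
               "self-links")
  expect_error(causal_graph(c("A", "B"),
                            data.frame(source = c("A", "A"), target = c("B", "B"),
                                       sign = c(1, -1))),
               "at most one link")
  expect_error(causal_graph("A", data.frame(source = "A", target = "Q", sign = 1)),
               "Q")
  expect_error(causal_graph(c("A", "B"),
                            data.frame(source = "A", target = "B", sign = 2)),
               "\\+1 or -1")
})

test_that("audit reports matching, wrong-polarity and absent loops", {
  g <- causal_graph(c("A", "B", "C"),
                    data.frame(source = c("A", "B", "B", "C"),
                               target = c("B", "A", "C", "B"),
                               sign = c(1, -1, 1, 1)))
  expected <- list(
    list(name = "ab", nodes = c("A", "B"), polarity = "balancing"),
    list(name = "bc", nodes = c("B", "C"), polarity = "balancing"),
    list(name = "ghost", nodes = c("A", "C"), polarity = "reinforcing"))
  aud <- audit_expected_loops(g, expected)
  expect_identical(aud$status,
                   c("found-with-matching-polarity", "found-wrong-polarity", "absent"))
  expect_identical(aud$found_polarity[[2L]], "reinforcing")
  expect_false(attr(aud, "passed"))
  aud_ok <- audit_expected_loops(g, expected[1L])
  expect_true(attr(aud_ok, "passed"))
})

test_that("audit collapses ignored pass-through nodes before matching", {
  # A -> f -> B -> A with f a pass-through (flow-like) node
  g <- causal_graph(c("A", "f", "B"),
                    data.frame(source = c("A", "f", "B"),
                               target = c("f", "B", "A"),
                               sign = c(1, -1, 1)))
  aud <- audit_expected_loops(
    g, list(list(name = "ab", nodes = c("A", "B"), polarity = "balancing")),
    ignore = "f")
  expect_true(attr(aud, "passed"))
})

test_that("causal-graph extraction follows the stock-flow sign conventions", {
  m <- sd_model("mini", horizon = list(start = 0, end = 2, dt = 1),
                stocks = list(sd_stock("S", 10)),
                flows = list(
                  sd_flow("f", "0.1 * S", source = "S", signs = c(S = 1)),
                  sd_flow("g", "c", sink = "S")),
                parameters = list(c = 1))
  g <- extract_causal_graph(m)
  expect_identical(link_sign_of(g, "S", "f"), 1)
  expect_identical(link_sign_of(g, "f", "S"), -1)
  expect_identical(link_sign_of(g, "g", "S"), 1)
  # parameter c is exogenous: no node, no link
  expect_false("c" %in% g$nodes)
  expect_identical(nrow(g$links), 3L)
})

test_that("extraction demands sign annotations for variable dependencies", {
  m <- sd_model("mini", horizon = list(start = 0, end = 2, dt = 1),
                stocks = list(sd_stock("S", 10)),
                flows = list(sd_flow("f", "0.1 * S", source = "S")))
  expect_error(extract_causal_graph(m), "S -> f")
})

test_that("DOT export labels negative links and dashes balancing-only edges", {
  g <- causal_graph(c("A", "B"),
                    data.frame(source = c("A", "B"), target = c("B", "A"),
                               sign = c(1, -1)))
  dot <- export_dot(g, enumerate_loops(g))
  expect_match(dot, "digraph")
  expect_match(dot, "label=\"-\"")
  expect_match(dot, "style=dashed")
})

test_that("loop reports serialize to JSON with cycle, polarity and length", {
  g <- causal_graph(c("A", "B"),
                    data.frame(source = c("A", "B"), target = c("B", "A"),
                               sign = c(1, -1)))
  path <- withr::local_tempfile(fileext = ".json")
  write_loops_json(enumerate_loops(g), path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_length(doc, 1L)
  expect_identical(doc[[1L]]$polarity, "balancing")
  expect_identical(doc[[1L]]$length, 2L)
})
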