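test_that("the Hoeffding bound matches its closed form and scaling laws", {
  expect_equal(hoeffding_bound(1, 1, 100), 0)
  # independent one-line evaluation
  expect_equal(hoeffding_bound(1, 0.05, 1000), sqrt(log(20) / 2000),
               tolerance = 1e-12)
  # 1/sqrt(n): quadrupling n halves the bound
  expect_equal(hoeffding_bound(1, 0.05, 400), hoeffding_bound(1, 0.05, 100) / 2)
  # monotone: decreasing in n and delta, increasing in R
  expect_gt(hoeffding_bound(1, 0.05, 100), hoeffding_bound(1, 0.05, 101))
  expect_gt(hoeffding_bound(1, 0.01, 100), hoeffding_bound(1, 0.05, 100))
  expect_gt(hoeffding_bound(2, 0.05, 100), hoeffding_bound(1, 0.05, 100))
  expect_error(hoeffding_bound(1, 0, 10), "delta")
  expect_error(hoeffding_bound(1, 1.5, 10), "delta")
  expect_error(hoeffding_bound(1, 0.5, 0), "count")
})

test_that("information gain has its closed-form values", {
  expect_equal(information_gain(rbind(c(50, 0), c(0, 50))), 1)   # pure split, 1 bit
  expect_equal(information_gain(rbind(c(25, 25), c(25, 25))), 0) # parent reproduced
  expect_equal(information_gain(rbind(c(30, 0), c(20, 0))), 0)   # single class
  expect_equal(information_gain(matrix(0, 2, 2)), 0)
  expect_error(information_gain(rbind(c(-1, 2), c(1, 1))), "non-negative")
})

test_that("incremental nominal gains equal batch entropy gains", {
  schema <- stream_schema(
    list(attribute_spec("v", "nominal", c("p", "q", "r", "s"))),
    attribute_spec("class", "nominal", c("a", "b", "c")))
  set.seed(77)
  for (rep in 1:100) {
    nr <- sample(2:4, 1)
    nc <- sample(2:3, 1)
    tab <- matrix(rpois(4 * 3, 3), 4, 3)
    if (nr < 4) tab[(nr + 1):4, ] <- 0
    if (nc < 3) tab[, (nc + 1):3] <- 0
    if (sum(tab) == 0) tab[1, 1] <- 1
    m <- hoeffding_tree(schema, grace = 1e9)
    for (v in 1:4) for (cl in 1:3) {
      for (k in seq_len(tab[v, cl])) {
        odrstream:::ht_train(m, as.numeric(v), cl)
      }
    }
    leaf <- m$root
    M <- leaf$nom[["1"]]
    expect_equal(unname(M), unname(tab))
    expect_equal(information_gain(M), oracle_gain(tab), tolerance = 1e-12)
  }
})

test_that("candidate thresholds form a strict interior grid", {
  expect_equal(candidate_thresholds(0, 10, 9), 1:9)
  expect_equal(candidate_thresholds(5, 5, 10), numeric(0))
  expect_equal(candidate_thresholds(0, 1, 1), 0.5)
  g <- candidate_thresholds(-2, 7, 10)
  expect_length(g, 10)
  expect_true(all(g > -2 & g < 7))
})

test_that("trivial learning cases behave as documented", {
  schema <- two_attr_schema()
  m <- hoeffding_tree(schema)
  # untrained model: first class, uniform scores
  p0 <- predict_one(m, data.frame(x1 = 0.5, x2 = 0.5))
  expect_equal(p0$label, "a")
  expect_equal(unname(p0$scores), c(0.5, 0.5))
  # one instance: single leaf predicting that class
  learn_one(m, data.frame(x1 = 1, x2 = 2), "b")
  expect_equal(tree_size(m), 1L)
  expect_equal(predict_one(m, data.frame(x1 = 9, x2 = 9))$label, "b")
  # a one-class stream never splits
  for (i in 1:600) learn_one(m, data.frame(x1 = runif(1), x2 = runif(1)), "b")
  expect_equal(tree_size(m), 1L)
  # majority tie breaks toward schema order
  m2 <- hoeffding_tree(schema)
  learn_one(m2, data.frame(x1 = 0, x2 = 0), "b")
  learn_one(m2, data.frame(x1 = 0, x2 = 0), "a")
  expect_equal(predict_one(m2, data.frame(x1 = 0, x2 = 0))$label, "a")
  expect_error(learn_one(m2, data.frame(x1 = 0, x2 = 0), "zz"), "class levels")
})

test_that("the first split lands on the informative attribute", {
  for (sd in 1:10) {
    set.seed(sd)
    schema <- two_attr_schema()
    m <- hoeffding_tree(schema)
    for (i in 1:400) {
      cl <- sample(c("a", "b"), 1)
      learn_one(m, data.frame(x1 = (cl == "b") + rnorm(1, 0, 0.01),
                              x2 = runif(1)), cl)
    }
    expect_false(m$root$is_leaf)
    expect_equal(m$root$attr, 1L)
  }
})

test_that("clone attributes split via the adaptive tie rule, lowest index first", {
  schema <- two_attr_schema()
  m <- hoeffding_tree(schema)
  cls <- rep(c(1L, 2L), 200)
  for (i in seq_along(cls)) {
    v <- as.numeric(cls[i] - 1L)
    odrstream:::ht_train(m, c(v, v), cls[i])
  }
  # first attempt at n=200: eps equals its own running mean, no tie split;
  # second attempt at n=400: eps drops below the mean and the tie fires
  expect_false(m$root$is_leaf)
  expect_equal(m$root$attr, 1L)
  expect_equal(tree_size(m), 3L)
  # trace the bound mean analytically
  e1 <- hoeffding_bound(1, m$delta, 200)
  e2 <- hoeffding_bound(1, m$delta, 400)
  expect_lt(e2, (e1 + e2) / 2)
  expect_equal(m$bound_sum / m$bound_n, (e1 + e2) / 2)
})

test_that("node counts satisfy the binary-split identity under traversal", {
  stream <- generate_stream(synth_config(n_instances = 5000, noise_rate = 0,
                                         seed = 13))
  m <- hoeffding_tree(stream$schema)
  comp <- odrstream:::compile_stream(stream)
  for (i in seq_len(nrow(comp$X))) odrstream:::ht_train(m, comp$X[i, ], comp$y[i])
  expect_gt(m$n_splits, 0L)
  expect_equal(tree_size(m), 2L * m$n_splits + 1L)  # all splits binary here
  expect_equal(tree_size(m), m$n_nodes)
  expect_equal(m$n_leaves, m$n_splits + 1L)
})

test_that("identical streams grow identical trees", {
  stream <- generate_stream(synth_config(n_instances = 3000, seed = 17))
  comp <- odrstream:::compile_stream(stream)
  grow <- function() {
    m <- hoeffding_tree(stream$schema)
    for (i in seq_len(nrow(comp$X))) odrstream:::ht_train(m, comp$X[i, ], comp$y[i])
    tree_to_list(m)
  }
  expect_identical(grow(), grow())
})

test_that("a depth-2 concept is learned to high prequential accuracy", {
  hits <- 0L
  for (sd in 1:10) {
    s <- generate_stream(synth_config(n_instances = 10000, concept_depth = 2,
                                      noise_rate = 0, seed = sd))
    r <- run_stream(s, run_config(seed = sd, odr = FALSE))
    hits <- hits + (r$finals$accuracy >= 0.9)
  }
  expect_gte(hits, 8L)
})

test_that("missing split attributes follow the majority branch", {
  schema <- two_attr_schema()
  m <- hoeffding_tree(schema)
  set.seed(3)
  for (i in 1:600) {
    cl <- sample(c("a", "b"), 1)
    learn_one(m, data.frame(x1 = (cl == "b") + rnorm(1, 0, 0.01),
                            x2 = runif(1)), cl)
  }
  expect_false(m$root$is_leaf)
  pred <- predict_one(m, data.frame(x1 = NA_real_, x2 = 0.5))
  maj <- which.max(m$root$child_n)
  expect_equal(pred$label,
               predict_one(m, data.frame(
                 x1 = if (maj == 1L) m$root$threshold - 1 else m$root$threshold + 1,
                 x2 = 0.5))$label)
})

test_that("nb_adaptive leaves fall back sensibly and stay valid", {
  schema <- two_attr_schema()
  m <- hoeffding_tree(schema, leaf_mode = "nb_adaptive")
  set.seed(8)
  for (i in 1:500) {
    cl <- sample(c("a", "b"), 1)
    learn_one(m, data.frame(x1 = (cl == "b") + rnorm(1, 0, 0.05),
                            x2 = runif(1)), cl)
  }
  p <- predict_one(m, data.frame(x1 = 1, x2 = 0.5))
  expect_equal(p$label, "b")
  expect_equal(sum(p$scores), 1, tolerance = 1e-9)
})

test_that("the cost balance is a monotone weighted sum on [0, 1]", {
  expect_equal(cost_balance(1, 0, 0, size_range = c(0, 10), time_range = c(0, 10)), 0)
  expect_equal(cost_balance(0.5, 0.5, 0.5), 0.5)
  base <- cost_balance(0.9, 0.4, 0.2)
  expect_gt(cost_balance(0.8, 0.4, 0.2), base)
  expect_gt(cost_balance(0.9, 0.5, 0.2), base)
  expect_gt(cost_balance(0.9, 0.4, 0.3), base)
  expect_error(cost_balance(1, 1, 1, weights = c(1, 1, 1)), "summing to 1")
})

test_that("serialization reflects the grown structure", {
  schema <- two_attr_schema()
  m <- hoeffding_tree(schema)
  lst <- tree_to_list(m)
  expect_equal(lst$n_nodes, 1L)
  expect_equal(lst$root$type, "leaf")
  set.seed(5)
  for (i in 1:400) {
    cl <- sample(c("a", "b"), 1)
    learn_one(m, data.frame(x1 = (cl == "b"), x2 = 0), cl)
  }
  lst2 <- tree_to_list(m)
  expect_equal(lst2$root$type, "split")
  expect_length(lst2$root$children, 2L)
  expect_silent(jsonlite::toJSON(lst2, auto_unbox = TRUE))
})
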