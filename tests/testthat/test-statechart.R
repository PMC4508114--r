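test_that("validate_chart reports structural violations as data", {
  ok <- sc_chart(sc_state("root"))
  expect_identical(validate_chart(ok), character())

  no_initial <- sc_chart(sc_state("root", "compound",
                                  children = list(sc_state("A"))))
  v <- validate_chart(no_initial)
  expect_length(v, 1)
  expect_match(v, "no initial child")
  expect_match(v, "root")

  bad_target <- sc_chart(
    sc_state("root", "compound", initial = "A",
             children = list(sc_state("A"))),
    list(sc_transition("t1", "A", "ghost", "go"))
  )
  v <- validate_chart(bad_target)
  expect_length(v, 1)
  expect_match(v, "t1")
  expect_match(v, "ghost")

  thin_region <- sc_chart(
    sc_state("root", "orthogonal", children = list(
      sc_state("R1", "compound", initial = "A", children = list(sc_state("A")))
    ))
  )
  expect_match(validate_chart(thin_region), "fewer than 2 regions")
  expect_error(enter_initial(thin_region), "invalid chart")
})

test_that("enter_initial performs recursive default completion", {
  flat <- sc_chart(sc_state("root", "compound", initial = "A",
                            children = list(sc_state("A"), sc_state("B"))))
  expect_setequal(configuration(enter_initial(flat)), c("root", "A"))

  ortho <- sc_chart(sc_state("root", "orthogonal", children = list(
    sc_state("R1", "compound", initial = "A",
             children = list(sc_state("A"), sc_state("B"))),
    sc_state("R2", "compound", initial = "C",
             children = list(sc_state("C"), sc_state("D")))
  )))
  expect_setequal(configuration(enter_initial(ortho)),
                  c("root", "R1", "A", "R2", "C"))

  lone <- sc_chart(sc_state("root"))
  expect_identical(configuration(enter_initial(lone)), "root")
})

test_that("is_in answers membership and rejects unknown states", {
  ch <- sc_chart(sc_state("root", "compound", initial = "A",
                          children = list(sc_state("A"), sc_state("B"))))
  inst <- enter_initial(ch)
  expect_true(is_in(inst, "A"))
  expect_false(is_in(inst, "B"))
  expect_true(is_in(inst, "root"))
  expect_error(is_in(inst, "nope"), "unknown state")
})

test_that("dispatch fires single transitions and ignores unmatched events", {
  ch <- sc_chart(
    sc_state("root", "compound", initial = "A",
             children = list(sc_state("A"), sc_state("B"))),
    list(sc_transition("t1", "A", "B", "e", actions = c("a1", "a2")))
  )
  inst <- enter_initial(ch)
  res <- dispatch(inst, "e")
  expect_setequal(configuration(res$instance), c("root", "B"))
  expect_identical(res$actions, c("a1", "a2"))

  res2 <- dispatch(res$instance, "e")
  expect_identical(configuration(res2$instance), configuration(res$instance))
  expect_identical(res2$actions, character())

  res3 <- dispatch(inst, "unknown-event")
  expect_setequal(configuration(res3$instance), c("root", "A"))
})

test_that("orthogonal regions each fire at most one transition per event", {
  ch <- sc_chart(
    sc_state("root", "orthogonal", children = list(
      sc_state("R1", "compound", initial = "A",
               children = list(sc_state("A"), sc_state("B"))),
      sc_state("R2", "compound", initial = "C",
               children = list(sc_state("C"), sc_state("D")))
    )),
    list(sc_transition("t1", "A", "B", "e"),
         sc_transition("t2", "C", "D", "e"))
  )
  res <- dispatch(enter_initial(ch), "e")
  expect_setequal(configuration(res$instance), c("root", "R1", "B", "R2", "D"))
})

test_that("inner transitions take priority over ancestors; ids break ties", {
  ch <- sc_chart(
    sc_state("root", "compound", initial = "outer", children = list(
      sc_state("outer", "compound", initial = "in1",
               children = list(sc_state("in1"), sc_state("in2"))),
      sc_state("other")
    )),
    list(sc_transition("t1", "outer", "other", "e"),
         sc_transition("t2", "in1", "in2", "e"))
  )
  res <- dispatch(enter_initial(ch), "e")
  expect_setequal(configuration(res$instance), c("root", "outer", "in2"))

  tie <- sc_chart(
    sc_state("root", "compound", initial = "A",
             children = list(sc_state("A"), sc_state("B"), sc_state("C"))),
    list(sc_transition("t2", "A", "C", "e"),
         sc_transition("t1", "A", "B", "e"))
  )
  res <- dispatch(enter_initial(tie), "e")
  expect_setequal(configuration(res$instance), c("root", "B"))
})

test_that("exit and entry follow least-common-ancestor semantics", {
  ch <- sc_chart(
    sc_state("root", "compound", initial = "P", children = list(
      sc_state("P", "compound", initial = "P1",
               children = list(sc_state("P1"), sc_state("P2"))),
      sc_state("Q", "compound", initial = "Q1",
               children = list(sc_state("Q1"), sc_state("Q2")))
    )),
    list(sc_transition("t1", "P1", "Q2", "jump"),
         sc_transition("t2", "Q", "Q", "self"))
  )
  inst <- enter_initial(ch)
  res <- dispatch(inst, "jump")
  expect_setequal(configuration(res$instance), c("root", "Q", "Q2"))
  # self-transition on Q exits the subtree and re-enters the default child
  res2 <- dispatch(res$instance, "self")
  expect_setequal(configuration(res2$instance), c("root", "Q", "Q1"))
})

test_that("guards gate transitions and failures name the transition", {
  ch <- sc_chart(
    sc_state("root", "compound", initial = "A",
             children = list(sc_state("A"), sc_state("B"))),
    list(sc_transition("t1", "A", "B", "e", guard = "go")),
    guards = list(go = function(ctx) isTRUE(ctx$ok))
  )
  inst <- enter_initial(ch)
  blocked <- dispatch(inst, "e", list(ok = FALSE))
  expect_setequal(configuration(blocked$instance), c("root", "A"))
  passed <- dispatch(inst, "e", list(ok = TRUE))
  expect_setequal(configuration(passed$instance), c("root", "B"))

  bad <- sc_chart(
    sc_state("root", "compound", initial = "A",
             children = list(sc_state("A"), sc_state("B"))),
    list(sc_transition("t9", "A", "B", "e", guard = "boom")),
    guards = list(boom = function(ctx) stop("kaput"))
  )
  expect_error(dispatch(enter_initial(bad), "e"), "t9")
  missing <- sc_chart(
    sc_state("root", "compound", initial = "A",
             children = list(sc_state("A"), sc_state("B"))),
    list(sc_transition("t5", "A", "B", "e", guard = "nowhere"))
  )
  expect_error(dispatch(enter_initial(missing), "e"), "not registered")
})

test_that("configuration consistency holds along random flat trajectories", {
  set.seed(42)
  for (rep in 1:20) {
    ch <- random_flat_chart(sample(2:5, 1), sample(1:10, 1))
    inst <- enter_initial(ch)
    for (ev in sample(c("e1", "e2", "e3"), 30, replace = TRUE)) {
      inst <- dispatch(inst, ev)$instance
      expect_identical(check_configuration(inst), character())
    }
  }
})

test_that("flat-chart trajectories match the transition-table oracle", {
  set.seed(7)
  events <- c("e1", "e2", "e3")
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    ch <- random_flat_chart(n, sample(1:10, 1), events)
    tab <- flat_transition_table(n, ch$transitions, events)
    seqs <- replicate(5, sample(events, 30, replace = TRUE), simplify = FALSE)
    for (s in seqs) {
      expect_identical(engine_simulate(ch, s), table_simulate(tab, "S1", s))
    }
  }
})

test_that("orthogonal regions behave as the product of independent machines", {
  k <- 3
  ch <- toggle_regions_chart(k)
  singles <- lapply(seq_len(k), function(i) {
    sc_chart(sc_state("root", "compound", initial = sprintf("A%d", i),
                      children = list(sc_state(sprintf("A%d", i)),
                                      sc_state(sprintf("B%d", i)))),
             list(sc_transition("f", sprintf("A%d", i), sprintf("B%d", i),
                                sprintf("ev%d", i)),
                  sc_transition("g", sprintf("B%d", i), sprintf("A%d", i),
                                sprintf("ev%d", i))))
  })
  set.seed(11)
  evs <- sample(sprintf("ev%d", seq_len(k)), 60, replace = TRUE)
  inst <- enter_initial(ch)
  insts <- lapply(singles, enter_initial)
  for (ev in evs) {
    inst <- dispatch(inst, ev)$instance
    insts <- lapply(insts, function(i) dispatch(i, ev)$instance)
    combined <- setdiff(configuration(inst),
                        c("root", sprintf("R%d", seq_len(k))))
    product <- unlist(lapply(insts, function(i) setdiff(configuration(i), "root")))
    expect_setequal(combined, product)
  }
})

test_that("dispatch is deterministic for identical inputs", {
  ch <- tumor_chart()
  inst <- enter_initial(ch)
  ctx <- list(o2 = 0.05, free = 2L, hyp = 3L, p = tumor_params())
  r1 <- dispatch(inst, "tick", ctx)
  r2 <- dispatch(inst, "tick", ctx)
  expect_identical(configuration(r1$instance), configuration(r2$instance))
  expect_identical(r1$actions, r2$actions)
})

test_that("chart files load from YAML and JSON and invalid files are rejected", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "states:",
    "  id: root",
    "  kind: compound",
    "  initial: idle",
    "  children:",
    "    - id: idle",
    "    - id: busy",
    "transitions:",
    "  - {id: t1, source: idle, target: busy, trigger: start}",
    "  - {id: t2, source: busy, target: idle, trigger: stop, actions: [done]}"
  ), yml)
  ch <- load_chart(yml)
  inst <- dispatch(enter_initial(ch), "start")$instance
  expect_true(is_in(inst, "busy"))
  res <- dispatch(inst, "stop")
  expect_identical(res$actions, "done")

  jsn <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    states = list(id = "root", kind = "compound", initial = "a",
                  children = list(list(id = "a"), list(id = "b"))),
    transitions = list(list(id = "t1", source = "a", target = "b",
                            trigger = "go"))
  ), auto_unbox = TRUE), jsn)
  chj <- load_chart(jsn)
  expect_true(is_in(dispatch(enter_initial(chj), "go")$instance, "b"))

  bad <- tempfile(fileext = ".yaml")
  writeLines(c(
    "states:",
    "  id: root",
    "  kind: compound",
    "  children:",
    "    - id: a",
    "transitions:",
    "  - {id: t1, source: a, target: ghost, trigger: go}"
  ), bad)
  expect_error(load_chart(bad), "invalid")
})
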