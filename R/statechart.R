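#' Hierarchical statechart engine
#'
#' A small, deterministic execution engine for hierarchical state machines
#' with orthogonal (concurrent) regions.  Charts are static definitions
#' ([sc_chart()]); each agent owns a live configuration ([enter_initial()],
#' an `sc_instance`) and receives events through [dispatch()].  Semantics
#' follow the UML family: default-completion entry, least-common-ancestor
#' exit/entry, inner-first conflict resolution, and run-to-completion
#' processing of one event at a time.
#'
#' @name statechart
NULL

#' Define a state node
#'
#' @param id state identifier (non-empty string, unique within a chart)
#' @param kind `"basic"` (leaf), `"compound"` (XOR children, one active at a
#'   time) or `"orthogonal"` (AND children: every region active together;
#'   regions must themselves be compound)
#' @param children list of child `sc_state` objects
#' @param initial id of the default child (compound nodes only)
#' @return an `sc_state` tree node
#' @export
sc_state <- function(id, kind = c("basic", "compound", "orthogonal"),
                     children = list(), initial = NULL) {
  kind <- match.arg(kind)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("state id must be a non-empty string", call. = FALSE)
  }
  structure(list(id = id, kind = kind, children = children, initial = initial),
            class = "sc_state")
}

#' Define a transition
#'
#' @param id transition identifier (unique within a chart; ties among
#'   equally-deep enabled transitions are broken by lexicographic id order)
#' @param source,target state ids
#' @param trigger event name enabling the transition
#' @param guard optional name of a predicate registered with the chart; the
#'   predicate receives the dispatch context and must return `TRUE`/`FALSE`
#' @param actions character vector of action tags returned by [dispatch()]
#'   when the transition fires
#' @return an `sc_transition`
#' @export
sc_transition <- function(id, source, target, trigger,
                          guard = NULL, actions = character()) {
  structure(list(id = as.character(id), source = as.character(source),
                 target = as.character(target), trigger = as.character(trigger),
                 guard = guard, actions = as.character(actions)),
            class = "sc_transition")
}

#' Build a statechart definition
#'
#' Flattens the state tree, runs structural validation, and (when valid)
#' precomputes the static data used by [dispatch()]: per-node depth,
#' ancestor/descendant tables, the default-completion configuration, and for
#' every transition its exit scope and entry set under least-common-ancestor
#' semantics.
#'
#' @param root an [sc_state()] tree
#' @param transitions list of [sc_transition()]
#' @param guards named list of guard predicates, `function(context)`
#' @return an `sc_chart`; inspect [validate_chart()] before executing it
#' @export
sc_chart <- function(root, transitions = list(), guards = list()) {
  nodes <- list()
  walk <- function(node, parent) {
    nodes[[length(nodes) + 1L]] <<- list(
      id = node$id, kind = node$kind, parent = parent,
      initial = if (is.null(node$initial)) NA_character_ else node$initial,
      child_ids = vapply(node$children, function(ch) ch$id, character(1))
    )
    for (ch in node$children) walk(ch, node$id)
  }
  walk(root, NA_character_)

  chart <- list(
    node_id = vapply(nodes, `[[`, character(1), "id"),
    kind    = vapply(nodes, `[[`, character(1), "kind"),
    parent_id = vapply(nodes, `[[`, character(1), "parent"),
    initial_id = vapply(nodes, `[[`, character(1), "initial"),
    child_ids = lapply(nodes, `[[`, "child_ids"),
    transitions = transitions,
    guards = guards
  )
  class(chart) <- "sc_chart"
  chart$violations <- sc_validate_structure(chart)
  if (length(chart$violations) == 0L) chart <- sc_precompute(chart)
  chart
}

# Structural validation; returns character vector of violations in a
# deterministic order (nodes by id, then transitions by id).
sc_validate_structure <- function(chart) {
  v <- character()
  ids <- chart$node_id
  dup <- unique(ids[duplicated(ids)])
  for (d in sort(dup)) v <- c(v, sprintf("duplicate state id '%s'", d))

  ord <- order(ids)
  for (i in ord) {
    id <- ids[i]
    kids <- chart$child_ids[[i]]
    kind <- chart$kind[i]
    if (kind == "basic" && length(kids) > 0L) {
      v <- c(v, sprintf("basic state '%s' has children", id))
    }
    if (kind == "compound") {
      if (length(kids) < 1L) {
        v <- c(v, sprintf("compound state '%s' has no children", id))
      }
      ini <- chart$initial_id[i]
      if (is.na(ini)) {
        v <- c(v, sprintf("compound state '%s' has no initial child", id))
      } else if (!(ini %in% kids)) {
        v <- c(v, sprintf("initial '%s' of state '%s' is not one of its children",
                          ini, id))
      }
    }
    if (kind == "orthogonal") {
      if (length(kids) < 2L) {
        v <- c(v, sprintf("orthogonal state '%s' has fewer than 2 regions", id))
      }
      for (k in kids) {
        ki <- match(k, ids)
        if (!is.na(ki) && chart$kind[ki] != "compound") {
          v <- c(v, sprintf("region '%s' of orthogonal state '%s' is not compound",
                            k, id))
        }
      }
    }
  }

  tids <- vapply(chart$transitions, `[[`, character(1), "id")
  dup <- unique(tids[duplicated(tids)])
  for (d in sort(dup)) v <- c(v, sprintf("duplicate transition id '%s'", d))
  for (j in order(tids)) {
    tr <- chart$transitions[[j]]
    if (!(tr$source %in% ids)) {
      v <- c(v, sprintf("transition '%s' has unknown source '%s'", tr$id, tr$source))
    }
    if (!(tr$target %in% ids)) {
      v <- c(v, sprintf("transition '%s' has unknown target '%s'", tr$id, tr$target))
    }
    if (!nzchar(tr$trigger)) {
      v <- c(v, sprintf("transition '%s' has an empty trigger", tr$id))
    }
  }
  v
}

# Precompute dispatch tables (valid charts only).
sc_precompute <- function(chart) {
  n <- length(chart$node_id)
  ids <- chart$node_id
  parent <- match(chart$parent_id, ids)           # int or NA (root)
  children <- lapply(chart$child_ids, match, ids)  # list of int
  initial <- match(chart$initial_id, ids)

  depth <- integer(n)
  anc_self <- vector("list", n)   # path root..self (ints)
  for (i in seq_len(n)) {
    path <- i
    p <- parent[i]
    while (!is.na(p)) { path <- c(p, path); p <- parent[p] }
    anc_self[[i]] <- path
    depth[i] <- length(path) - 1L
  }

  desc <- vector("list", n)       # self + all descendants
  collect <- function(i) {
    out <- i
    for (c in children[[i]]) out <- c(out, collect(c))
    out
  }
  for (i in seq_len(n)) desc[[i]] <- collect(i)

  is_anc <- matrix(FALSE, n, n)   # is_anc[a, b]: a is ancestor-or-self of b
  for (b in seq_len(n)) is_anc[anc_self[[b]], b] <- TRUE

  # default completion below / including a node
  complete_set <- function(i) {
    out <- i
    if (chart$kind[i] == "compound") out <- c(out, complete_set(initial[i]))
    if (chart$kind[i] == "orthogonal") {
      for (r in children[[i]]) out <- c(out, complete_set(r))
    }
    out
  }
  init_active <- logical(n)
  init_active[complete_set(1L)] <- TRUE

  trs <- chart$transitions
  tr_pre <- vector("list", length(trs))
  for (j in seq_along(trs)) {
    tr <- trs[[j]]
    s <- match(tr$source, ids); t <- match(tr$target, ids)
    ps <- anc_self[[s]]; pt <- anc_self[[t]]
    m <- min(length(ps), length(pt))
    common <- which(ps[seq_len(m)] == pt[seq_len(m)])
    lca <- ps[max(common)]
    if (lca == s || lca == t) {
      exit_node <- lca
    } else {
      exit_node <- ps[depth[lca] + 2L]
    }
    # entry set
    if (lca == t) {
      entry <- complete_set(t)
    } else {
      chain <- pt[(depth[lca] + 2L):length(pt)]
      if (lca == s) chain <- c(s, chain)
      entry <- integer()
      for (k in seq_along(chain)) {
        nd <- chain[k]
        entry <- c(entry, nd)
        if (k < length(chain)) {
          if (chart$kind[nd] == "orthogonal") {
            for (r in children[[nd]]) {
              if (r != chain[k + 1L]) entry <- c(entry, complete_set(r))
            }
          }
        } else {
          if (chart$kind[nd] == "compound") entry <- c(entry, complete_set(initial[nd]))
          if (chart$kind[nd] == "orthogonal") {
            for (r in children[[nd]]) entry <- c(entry, complete_set(r))
          }
        }
      }
    }
    tr_pre[[j]] <- list(id = tr$id, source = s, target = t,
                        trigger = tr$trigger, guard = tr$guard,
                        actions = tr$actions, exit_node = exit_node,
                        entry = unique(entry), src_depth = depth[s])
  }

  by_trigger <- list()
  if (length(tr_pre)) {
    trig <- vapply(tr_pre, `[[`, character(1), "trigger")
    sdep <- vapply(tr_pre, `[[`, integer(1), "src_depth")
    tid <- vapply(tr_pre, `[[`, character(1), "id")
    for (ev in unique(trig)) {
      idx <- which(trig == ev)
      by_trigger[[ev]] <- idx[order(-sdep[idx], tid[idx])]
    }
  }

  chart$parent <- parent
  chart$children <- children
  chart$initial <- initial
  chart$depth <- depth
  chart$anc_self <- anc_self
  chart$desc <- desc
  chart$is_anc <- is_anc
  chart$init_active <- init_active
  chart$tr <- tr_pre
  chart$by_trigger <- by_trigger
  chart$basic <- which(chart$kind == "basic")
  chart
}

#' Validate a statechart definition
#'
#' @param chart an `sc_chart`
#' @return character vector of violation descriptions; empty when the chart
#'   is structurally valid.  Violations are data, not errors: the chart
#'   object can be inspected, it just cannot be executed.
#' @export
validate_chart <- function(chart) {
  stopifnot(inherits(chart, "sc_chart"))
  chart$violations
}

sc_assert_valid <- function(chart) {
  if (length(chart$violations) > 0L) {
    stop(sprintf("invalid chart: %s", paste(chart$violations, collapse = "; ")),
         call. = FALSE)
  }
}

#' Enter the default configuration of a chart
#'
#' Activates the root and, recursively, the `initial` child of every active
#' compound node and every region of every active orthogonal node.
#'
#' @param chart a valid `sc_chart`
#' @return an `sc_instance` holding the live configuration
#' @export
enter_initial <- function(chart) {
  sc_assert_valid(chart)
  structure(list(chart = chart, active = chart$init_active),
            class = "sc_instance")
}

#' Active configuration of an instance
#' @param instance an `sc_instance`
#' @return character vector of active state ids (tree order)
#' @export
configuration <- function(instance) {
  instance$chart$node_id[instance$active]
}

#' Test whether a state is active
#' @param instance an `sc_instance`
#' @param state a state id present in the chart
#' @export
is_in <- function(instance, state) {
  i <- match(state, instance$chart$node_id)
  if (is.na(i)) stop(sprintf("unknown state id '%s'", state), call. = FALSE)
  instance$active[i]
}

# Innermost active basic state (unique for charts whose leaves are not under
# orthogonal nodes, e.g. the default tumor chart).
sc_leaf_state <- function(instance) {
  ch <- instance$chart
  b <- ch$basic[instance$active[ch$basic]]
  ch$node_id[b[1L]]
}

#' Dispatch one event into a chart instance
#'
#' Run-to-completion processing of a single event: every enabled transition
#' fires, except that conflicting transitions (overlapping exit scopes) are
#' resolved inner-first — a transition whose source is deeper wins — with
#' lexicographic transition-id order breaking ties.  At most one transition
#' fires per orthogonal region.  Exit and entry follow least-common-ancestor
#' semantics with default completion of entered compound/orthogonal states.
#'
#' An event with no matching transition is a no-op, not an error.  A guard
#' that errors, or returns anything other than a single `TRUE`/`FALSE`,
#' raises an error naming the transition.
#'
#' @param instance an `sc_instance`
#' @param event event name
#' @param context list passed to guard predicates
#' @return `list(instance = <updated instance>, actions = <character vector
#'   of fired action tags, in execution order>)`
#' @export
dispatch <- function(instance, event, context = list()) {
  chart <- instance$chart
  cand <- chart$by_trigger[[event]]
  if (is.null(cand)) {
    return(list(instance = instance, actions = character()))
  }
  active <- instance$active
  sel <- integer()
  sel_exit <- integer()
  is_anc <- chart$is_anc
  for (ti in cand) {
    tr <- chart$tr[[ti]]
    if (!active[tr$source]) next
    if (!is.null(tr$guard)) {
      g <- chart$guards[[tr$guard]]
      if (is.null(g)) {
        stop(sprintf("guard '%s' on transition '%s' is not registered",
                     tr$guard, tr$id), call. = FALSE)
      }
      res <- tryCatch(g(context), error = function(e) e)
      if (inherits(res, "error")) {
        stop(sprintf("guard '%s' on transition '%s' failed: %s",
                     tr$guard, tr$id, conditionMessage(res)), call. = FALSE)
      }
      if (!is.logical(res) || length(res) != 1L || is.na(res)) {
        stop(sprintf("guard '%s' on transition '%s' did not return TRUE/FALSE",
                     tr$guard, tr$id), call. = FALSE)
      }
      if (!res) next
    }
    ex <- tr$exit_node
    conflict <- FALSE
    for (e in sel_exit) {
      if (is_anc[e, ex] || is_anc[ex, e]) { conflict <- TRUE; break }
    }
    if (conflict) next
    sel <- c(sel, ti)
    sel_exit <- c(sel_exit, ex)
  }
  if (length(sel) == 0L) {
    return(list(instance = instance, actions = character()))
  }
  actions <- character()
  for (ti in sel) {
    tr <- chart$tr[[ti]]
    active[chart$desc[[tr$exit_node]]] <- FALSE
    active[tr$entry] <- TRUE
    if (length(tr$actions)) actions <- c(actions, tr$actions)
  }
  instance$active <- active
  list(instance = instance, actions = actions)
}

#' Check configuration consistency of an instance
#'
#' Verifies the configuration invariants: root active; exactly one active
#' child per active compound node; all regions active under an active
#' orthogonal node; no active node with an inactive ancestor.
#'
#' @param instance an `sc_instance`
#' @return character vector of violations (empty when consistent)
#' @export
check_configuration <- function(instance) {
  ch <- instance$chart
  a <- instance$active
  v <- character()
  if (!a[1L]) v <- c(v, "root is not active")
  for (i in seq_along(ch$node_id)) {
    if (a[i]) {
      p <- ch$parent[i]
      if (!is.na(p) && !a[p]) {
        v <- c(v, sprintf("state '%s' active under inactive parent", ch$node_id[i]))
      }
      if (ch$kind[i] == "compound") {
        nact <- sum(a[ch$children[[i]]])
        if (nact != 1L) {
          v <- c(v, sprintf("compound '%s' has %d active children", ch$node_id[i], nact))
        }
      }
      if (ch$kind[i] == "orthogonal") {
        if (!all(a[ch$children[[i]]])) {
          v <- c(v, sprintf("orthogonal '%s' has an inactive region", ch$node_id[i]))
        }
      }
    } else if (any(a[ch$desc[[i]]])) {
      v <- c(v, sprintf("inactive state '%s' has an active descendant", ch$node_id[i]))
    }
  }
  v
}

#' Load a chart definition from a YAML or JSON file
#'
#' The document must contain a `states:` tree (maps with `id`, `kind`,
#' optional `initial` and `children`) and an optional `transitions:` list
#' (maps with `id`, `source`, `target`, `trigger`, optional `guard` and
#' `actions`).  Files ending in `.json` are parsed as JSON, everything else
#' as YAML (of which JSON is a subset anyway).  A document that fails
#' [validate_chart()] is rejected with the full violation list.
#'
#' @param path file path
#' @param guards named list of guard predicates to register
#' @return a valid `sc_chart`
#' @export
load_chart <- function(path, guards = list()) {
  if (!file.exists(path)) stop(sprintf("chart file '%s' not found", path), call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$states)) stop("chart file has no 'states' entry", call. = FALSE)
  build <- function(nd) {
    if (is.null(nd$id)) stop("a state entry is missing 'id'", call. = FALSE)
    sc_state(as.character(nd$id),
             kind = if (is.null(nd$kind)) "basic" else as.character(nd$kind),
             children = lapply(nd$children %||% list(), build),
             initial = if (is.null(nd$initial)) NULL else as.character(nd$initial))
  }
  root <- build(doc$states)
  trs <- lapply(doc$transitions %||% list(), function(tr) {
    sc_transition(tr$id, tr$source, tr$target, tr$trigger,
                  guard = if (is.null(tr$guard)) NULL else as.character(tr$guard),
                  actions = unlist(tr$actions %||% character()))
  })
  chart <- sc_chart(root, trs, guards = guards)
  if (length(chart$violations) > 0L) {
    stop(sprintf("chart file '%s' is invalid: %s", path,
                 paste(chart$violations, collapse = "; ")), call. = FALSE)
  }
  chart
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sc_chart <- function(x, ...) {
  cat(sprintf("<sc_chart: %d states, %d transitions%s>\n",
              length(x$node_id), length(x$transitions),
              if (length(x$violations)) sprintf(", %d violations", length(x$violations)) else ""))
  invisible(x)
}

#' @export
print.sc_instance <- function(x, ...) {
  cat(sprintf("<sc_instance: {%s}>\n", paste(configuration(x), collapse = ", ")))
  invisible(x)
}
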