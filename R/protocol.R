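#' Reactive-animation wire protocol
#'
#' The simulator and a viewer exchange XML: the model side emits one XML
#' document per step containing object diffs (`create` / `update` /
#' `delete`), logged events and a `stats` element; the viewer side sends
#' commands (`set` / `kill` / `create` / `query` / `pause` / `speed`).
#' Recordings are newline-delimited streams — a header line followed by one
#' step document per line — so runs can be replayed later at any pacing.
#'
#' The schema is this package's own, versioned (`v1`); encoding is
#' byte-stable: fixed attribute order, no whitespace, reals rendered with
#' `%.9g`.  Decoders are strict: unknown elements or attributes are
#' rejected, not ignored.
#'
#' @name ra_protocol
NULL

PROTOCOL_VERSION <- "1"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

fmt_num <- function(x) {
  if (is.integer(x) || (is.numeric(x) && x == round(x) && abs(x) < 2^31)) {
    sprintf("%d", as.integer(x))
  } else {
    sprintf("%.9g", x)
  }
}

#' Construct a stream message
#'
#' @param kind `"create"`, `"update"`, `"delete"` or `"event"`
#' @param id object id (create/update/delete)
#' @param type `"tumor_cell"` or `"endothelial_cell"`
#' @param voxel integer 3-vector (create/update)
#' @param state state tag (create/update)
#' @param pred predecessor id for endothelial cells (`NA` for roots); used
#'   by viewers to render vessels as connected tubes
#' @param event,payload event name and named payload fields (`kind =
#'   "event"` only)
#' @return an `anim_message` list
#' @export
anim_message <- function(kind, id = NULL, type = NULL, voxel = NULL,
                         state = NULL, pred = NULL, event = NULL,
                         payload = list()) {
  m <- switch(kind,
    create = ,
    update = {
      m <- list(kind = kind, id = as.integer(id), type = type,
                x = as.integer(voxel[1]), y = as.integer(voxel[2]),
                z = as.integer(voxel[3]), state = state)
      if (type == "endothelial_cell") m$pred <- as.integer(pred)
      m
    },
    delete = list(kind = "delete", id = as.integer(id)),
    event = c(list(kind = "event", event = event), payload),
    stop(sprintf("unknown message kind '%s'", kind), call. = FALSE)
  )
  m
}

encode_message <- function(m) {
  switch(m$kind,
    create = ,
    update = {
      pred_attr <- if (!is.null(m$pred) && !is.na(m$pred)) {
        sprintf(' pred="%d"', m$pred)
      } else ""
      sprintf('<%s id="%d" type="%s" x="%d" y="%d" z="%d" state="%s"%s/>',
              m$kind, m$id, m$type, m$x, m$y, m$z, m$state, pred_attr)
    },
    delete = sprintf('<delete id="%d"/>', m$id),
    event = {
      extra <- setdiff(names(m), c("kind", "event"))
      attrs <- vapply(extra, function(nm) {
        sprintf(' %s="%s"', nm, xml_escape(fmt_num_or_chr(m[[nm]])))
      }, character(1))
      sprintf('<event kind="%s"%s/>', m$event, paste(attrs, collapse = ""))
    },
    stop(sprintf("cannot encode message kind '%s'", m$kind), call. = FALSE)
  )
}

fmt_num_or_chr <- function(x) if (is.numeric(x)) fmt_num(x) else as.character(x)

empty_stats <- function() {
  data.frame(type = character(), state = character(), n = integer(),
             stringsAsFactors = FALSE)
}

#' Encode one step document
#'
#' Produces a single-element XML document `<step t="...">` containing one
#' child per message followed by one `<stats>` element.  The message
#' ordering invariants are enforced: within a stream, `create` must precede
#' `update`/`delete` for an id and `delete` is terminal; within one
#' document this means no id is updated after being deleted, created after
#' being created, etc.
#'
#' @param step step index
#' @param messages list of [anim_message()]s
#' @param stats data.frame with columns `type`, `state`, `n`
#' @return a single string (one line, no internal whitespace)
#' @export
encode_step <- function(step, messages = list(), stats = empty_stats()) {
  seen <- new.env(parent = emptyenv())
  for (m in messages) {
    if (m$kind %in% c("create", "update", "delete")) {
      key <- as.character(m$id)
      prev <- seen[[key]]
      if (!is.null(prev)) {
        if (prev == "delete") {
          stop(sprintf("message after delete for id %d", m$id), call. = FALSE)
        }
        if (m$kind == "create") {
          stop(sprintf("duplicate create for id %d", m$id), call. = FALSE)
        }
      }
      seen[[key]] <- m$kind
    }
  }
  body <- vapply(messages, encode_message, character(1))
  stats_xml <- if (nrow(stats) == 0L) {
    "<stats/>"
  } else {
    rows <- sprintf('<count type="%s" state="%s" n="%d"/>',
                    stats$type, stats$state, as.integer(stats$n))
    sprintf("<stats>%s</stats>", paste(rows, collapse = ""))
  }
  sprintf('<step t="%d">%s%s</step>', as.integer(step),
          paste(body, collapse = ""), stats_xml)
}

decode_error <- function(msg) {
  stop(structure(class = c("oncosim_decode_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

need_attrs <- function(node, required, optional = character()) {
  at <- xml2::xml_attrs(node)
  nm <- names(at)
  missing <- setdiff(required, nm)
  if (length(missing)) {
    decode_error(sprintf("<%s> is missing attribute(s): %s",
                         xml2::xml_name(node), paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(nm, c(required, optional))
  if (length(unknown)) {
    decode_error(sprintf("<%s> has unknown attribute(s): %s",
                         xml2::xml_name(node), paste(unknown, collapse = ", ")))
  }
  at
}

as_int <- function(x, what) {
  v <- suppressWarnings(as.integer(x))
  if (is.na(v)) decode_error(sprintf("%s is not an integer: '%s'", what, x))
  v
}

#' Decode one step document
#'
#' Strict inverse of [encode_step()].  Malformed XML, unknown elements or
#' attributes, or a missing `stats` element raise a decode error.
#'
#' @param doc a string holding one `<step>` XML document
#' @return `list(step = index, messages = list, stats = data.frame)`
#' @export
decode_step <- function(doc) {
  x <- tryCatch(xml2::read_xml(doc),
                error = function(e) decode_error(sprintf("malformed XML: %s",
                                                         conditionMessage(e))))
  if (xml2::xml_name(x) != "step") {
    decode_error(sprintf("expected <step>, found <%s>", xml2::xml_name(x)))
  }
  at <- need_attrs(x, "t")
  step <- as_int(at[["t"]], "step index")
  messages <- list()
  stats <- NULL
  for (node in xml2::xml_children(x)) {
    nm <- xml2::xml_name(node)
    if (nm %in% c("create", "update")) {
      a <- need_attrs(node, c("id", "type", "x", "y", "z", "state"), "pred")
      if (!(a[["type"]] %in% c("tumor_cell", "endothelial_cell"))) {
        decode_error(sprintf("unknown object type '%s'", a[["type"]]))
      }
      m <- list(kind = nm, id = as_int(a[["id"]], "id"), type = a[["type"]],
                x = as_int(a[["x"]], "x"), y = as_int(a[["y"]], "y"),
                z = as_int(a[["z"]], "z"), state = a[["state"]])
      if (a[["type"]] == "endothelial_cell") {
        m$pred <- if ("pred" %in% names(a)) as_int(a[["pred"]], "pred") else NA_integer_
      } else if ("pred" %in% names(a)) {
        decode_error("pred attribute on a tumor_cell message")
      }
      messages[[length(messages) + 1L]] <- m
    } else if (nm == "delete") {
      a <- need_attrs(node, "id")
      messages[[length(messages) + 1L]] <-
        list(kind = "delete", id = as_int(a[["id"]], "id"))
    } else if (nm == "event") {
      a <- need_attrs(node, "kind",
                      c("path", "value", "id", "type", "mode", "x", "y", "z"))
      m <- list(kind = "event", event = a[["kind"]])
      for (f in setdiff(names(a), "kind")) {
        m[[f]] <- if (f %in% c("value")) as.numeric(a[[f]]) else
          if (f %in% c("id", "x", "y", "z")) as_int(a[[f]], f) else a[[f]]
      }
      messages[[length(messages) + 1L]] <- m
    } else if (nm == "stats") {
      if (!is.null(stats)) decode_error("duplicate <stats> element")
      kids <- xml2::xml_children(node)
      rows <- lapply(kids, function(k) {
        if (xml2::xml_name(k) != "count") {
          decode_error(sprintf("unknown element <%s> inside <stats>",
                               xml2::xml_name(k)))
        }
        a <- need_attrs(k, c("type", "state", "n"))
        data.frame(type = a[["type"]], state = a[["state"]],
                   n = as_int(a[["n"]], "n"), stringsAsFactors = FALSE)
      })
      stats <- if (length(rows)) do.call(rbind, rows) else empty_stats()
    } else {
      decode_error(sprintf("unknown element <%s> in step document", nm))
    }
  }
  if (is.null(stats)) decode_error("step document has no <stats> element")
  list(step = step, messages = messages, stats = stats)
}

#' Encode a command
#'
#' @param cmd a command list as returned by [decode_command()]
#' @return a single-line XML fragment
#' @export
encode_command <- function(cmd) {
  switch(cmd$kind,
    set_param = sprintf('<set param="%s" value="%s"/>',
                        xml_escape(cmd$path), fmt_num(cmd$value)),
    kill = if (!is.null(cmd$id)) {
      sprintf('<kill id="%d"/>', cmd$id)
    } else {
      sprintf('<kill type="%s" mode="random"/>', cmd$type)
    },
    create = sprintf('<create type="%s" x="%d" y="%d" z="%d"/>',
                     cmd$type, cmd$voxel[1], cmd$voxel[2], cmd$voxel[3]),
    query = sprintf('<query id="%d"/>', cmd$id),
    pause = "<pause/>",
    speed = sprintf('<speed factor="%s"/>', fmt_num(cmd$factor)),
    stop(sprintf("unknown command kind '%s'", cmd$kind), call. = FALSE)
  )
}

#' Decode an inbound command
#'
#' Accepted fragments: `<set param="..." value="..."/>`, `<kill id="..."/>`
#' or `<kill type="..." mode="random"/>`, `<create type="..." x y z/>`,
#' `<query id="..."/>`, `<pause/>`, `<speed factor="..."/>`.
#'
#' @param fragment a string holding one command element
#' @return a typed command list with a `kind` field
#' @export
decode_command <- function(fragment) {
  x <- tryCatch(xml2::read_xml(fragment),
                error = function(e) decode_error(sprintf("malformed command: %s",
                                                         conditionMessage(e))))
  nm <- xml2::xml_name(x)
  switch(nm,
    set = {
      a <- need_attrs(x, c("param", "value"))
      val <- suppressWarnings(as.numeric(a[["value"]]))
      if (is.na(val)) decode_error("set value is not numeric")
      list(kind = "set_param", path = a[["param"]], value = val)
    },
    kill = {
      a <- xml2::xml_attrs(x)
      if ("id" %in% names(a)) {
        a <- need_attrs(x, "id")
        list(kind = "kill", id = as_int(a[["id"]], "id"))
      } else {
        a <- need_attrs(x, c("type", "mode"))
        if (a[["mode"]] != "random") decode_error("kill mode must be 'random'")
        list(kind = "kill", type = a[["type"]], mode = "random")
      }
    },
    create = {
      a <- need_attrs(x, c("type", "x", "y", "z"))
      list(kind = "create", type = a[["type"]],
           voxel = c(as_int(a[["x"]], "x"), as_int(a[["y"]], "y"),
                     as_int(a[["z"]], "z")))
    },
    query = {
      a <- need_attrs(x, "id")
      list(kind = "query", id = as_int(a[["id"]], "id"))
    },
    pause = list(kind = "pause"),
    speed = {
      a <- need_attrs(x, "factor")
      f <- suppressWarnings(as.numeric(a[["factor"]]))
      if (is.na(f) || f <= 0) decode_error("speed factor must be positive")
      list(kind = "speed", factor = f)
    },
    decode_error(sprintf("unknown command <%s>", nm))
  )
}

#' Apply a decoded command to a running simulation
#'
#' `set_param` mutates a dotted parameter path (e.g. `"tumor.s_V"`,
#' `"angio.beta"`, `"baseline_o2"`) in the configuration for all subsequent
#' steps, revalidates it, and logs the change into the stream.  `kill`,
#' `create` and `query` delegate to the simulator operations.  `pause` and
#' `speed` only affect replay pacing and are acknowledged without touching
#' the state.  Command failures produce an error reply; the state and
#' config are left unchanged.
#'
#' @param state a `sim_state`
#' @param config the `sim_config` in force
#' @param cmd a command from [decode_command()]
#' @return `list(state, config, reply)` where `reply` is a one-line XML
#'   `<reply>` element
#' @export
apply_command <- function(state, config, cmd) {
  ok <- function(...) {
    fields <- list(...)
    attrs <- paste(vapply(names(fields), function(nm) {
      sprintf(' %s="%s"', nm, xml_escape(fmt_num_or_chr(fields[[nm]])))
    }, character(1)), collapse = "")
    sprintf('<reply status="ok"%s/>', attrs)
  }
  err <- function(msg) {
    list(state = state, config = config,
         reply = sprintf('<reply status="error" message="%s"/>', xml_escape(msg)))
  }
  tryCatch(
    switch(cmd$kind,
      set_param = {
        parts <- strsplit(cmd$path, ".", fixed = TRUE)[[1]]
        new_config <- config
        if (length(parts) == 1L) {
          if (!is.numeric(new_config[[parts[1]]]) || length(new_config[[parts[1]]]) != 1L) {
            return(err(sprintf("unknown parameter path '%s'", cmd$path)))
          }
          new_config[[parts[1]]] <- cmd$value
        } else if (length(parts) == 2L &&
                   parts[1] %in% c("tumor", "angio", "fields")) {
          block <- new_config[[parts[1]]]
          cur <- block[[parts[2]]]
          if (is.null(cur) || length(cur) != 1L) {
            return(err(sprintf("unknown parameter path '%s'", cmd$path)))
          }
          block[[parts[2]]] <- if (is.logical(cur)) as.logical(cmd$value) else cmd$value
          if (is.integer(cur)) block[[parts[2]]] <- as.integer(cmd$value)
          new_config[[parts[1]]] <- block
        } else {
          return(err(sprintf("unknown parameter path '%s'", cmd$path)))
        }
        v <- tryCatch({ validate_config(new_config); NULL },
                      error = function(e) conditionMessage(e))
        if (!is.null(v)) return(err(v))
        state$pending_events[[length(state$pending_events) + 1L]] <-
          anim_message("event", event = "set_param",
                       payload = list(path = cmd$path, value = cmd$value))
        list(state = state, config = new_config,
             reply = ok(kind = "set_param", path = cmd$path, value = cmd$value))
      },
      kill = {
        state <- kill_object(state, config, id = cmd$id, type = cmd$type)
        list(state = state, config = config, reply = ok(kind = "kill"))
      },
      create = {
        state <- create_object(state, config, cmd$type, cmd$voxel)
        list(state = state, config = config,
             reply = ok(kind = "create", id = state$next_id - 1L))
      },
      query = {
        info <- query_object(state, cmd$id)
        link <- if (info$type == "tumor_cell") info$parent else info$pred
        list(state = state, config = config,
             reply = ok(kind = "query", id = cmd$id, type = info$type,
                        x = info$voxel[1], y = info$voxel[2], z = info$voxel[3],
                        state = info$state,
                        parent = if (is.na(link)) "none" else as.character(link),
                        o2 = info$o2, vegf = info$vegf))
      },
      pause = list(state = state, config = config, reply = ok(kind = "pause")),
      speed = list(state = state, config = config,
                   reply = ok(kind = "speed", factor = cmd$factor)),
      err(sprintf("unknown command kind '%s'", cmd$kind))
    ),
    oncosim_command_error = function(e) err(conditionMessage(e))
  )
}

# ---- recording and replay ----------------------------------------------

# weak polynomial checksum of the canonical JSON form of a config; good
# enough to detect replaying a file against the wrong configuration
config_digest <- function(config) {
  strip <- unclass(config)
  strip$record_path <- NULL
  strip$tumor <- unclass(strip$tumor)
  strip$angio <- unclass(strip$angio)
  json <- jsonlite::toJSON(strip, auto_unbox = TRUE, digits = 10)
  bytes <- as.integer(charToRaw(as.character(json)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

encode_run_header <- function(config) {
  sprintf('<run version="%s" seed="%d" config="%s"/>',
          PROTOCOL_VERSION, config$seed, config_digest(config))
}

decode_run_header <- function(line) {
  x <- tryCatch(xml2::read_xml(line),
                error = function(e) decode_error("malformed recording header"))
  if (xml2::xml_name(x) != "run") decode_error("recording does not start with <run>")
  a <- need_attrs(x, c("version", "seed", "config"))
  if (a[["version"]] != PROTOCOL_VERSION) {
    decode_error(sprintf("unsupported recording version '%s' (expected '%s')",
                         a[["version"]], PROTOCOL_VERSION))
  }
  list(version = a[["version"]], seed = as_int(a[["seed"]], "seed"),
       config = a[["config"]])
}

#' Write a recording to a file
#'
#' @param recording `list(header = , steps = character vector)` of encoded
#'   lines, or the lines themselves
#' @param path output path (conventionally `*.ras.xml`)
#' @export
record <- function(recording, path) {
  lines <- if (is.list(recording)) c(recording$header, recording$steps) else recording
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(path)
}

#' Replay a recorded run
#'
#' Decodes a stream file produced by a recorded [sim_run()].  The speed
#' factor is a pacing hint for viewers; it never changes the decoded
#' content.
#'
#' @param path a recording file
#' @param speed pacing factor (> 0)
#' @return a `ras_replay`: `list(header, steps, speed)` where `steps` is a
#'   list of decoded step documents in order
#' @export
replay <- function(path, speed = 1) {
  if (!file.exists(path)) decode_error(sprintf("recording '%s' not found", path))
  if (speed <= 0) decode_error("speed factor must be positive")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) decode_error("empty recording")
  header <- decode_run_header(lines[1])
  steps <- vector("list", length(lines) - 1L)
  last_t <- -1L
  for (i in seq_along(steps)) {
    st <- tryCatch(decode_step(lines[i + 1L]), error = function(e) {
      decode_error(sprintf("replay failed at step line %d: %s", i,
                           conditionMessage(e)))
    })
    if (st$step <= last_t) {
      decode_error(sprintf("step indices not strictly increasing at line %d", i))
    }
    last_t <- st$step
    steps[[i]] <- st
  }
  structure(list(header = header, steps = steps, speed = speed),
            class = "ras_replay")
}

#' Reconstruct scenes from a replay
#'
#' Applies the create/update/delete messages of each step to an initially
#' empty scene and returns, per step, the set of live object tuples —
#' exactly what a viewer would display.
#'
#' @param rep a `ras_replay`
#' @return named list (by step index) of data.frames with columns
#'   `id, type, x, y, z, state`
#' @export
replay_scene <- function(rep) {
  scene <- list()
  out <- list()
  for (st in rep$steps) {
    for (m in st$messages) {
      if (m$kind == "create") {
        key <- as.character(m$id)
        if (!is.null(scene[[key]])) {
          decode_error(sprintf("create for existing id %d at step %d", m$id, st$step))
        }
        scene[[key]] <- m
      } else if (m$kind == "update") {
        key <- as.character(m$id)
        if (is.null(scene[[key]])) {
          decode_error(sprintf("update for unknown id %d at step %d", m$id, st$step))
        }
        m$kind <- "create"
        scene[[key]] <- m
      } else if (m$kind == "delete") {
        key <- as.character(m$id)
        if (is.null(scene[[key]])) {
          decode_error(sprintf("delete for unknown id %d at step %d", m$id, st$step))
        }
        scene[[key]] <- NULL
      }
    }
    ids <- as.integer(names(scene))
    ord <- order(ids)
    out[[as.character(st$step)]] <- data.frame(
      id = ids[ord],
      type = vapply(scene[ord], `[[`, character(1), "type"),
      x = vapply(scene[ord], `[[`, integer(1), "x"),
      y = vapply(scene[ord], `[[`, integer(1), "y"),
      z = vapply(scene[ord], `[[`, integer(1), "z"),
      state = vapply(scene[ord], `[[`, character(1), "state"),
      row.names = NULL
    )
  }
  out
}

# ---- live scene diffing (used by sim_run when recording) ----------------

live_scene <- function(state) {
  scene <- list()
  for (id in state$tumor_ids) {
    cell <- state$cells[[id]]
    scene[[as.character(id)]] <- list(id = id, type = "tumor_cell",
                                      x = cell$voxel[1], y = cell$voxel[2],
                                      z = cell$voxel[3], state = cell$state,
                                      pred = NA_integer_)
  }
  for (id in state$network$order) {
    cell <- state$network$cells[[id]]
    scene[[as.character(id)]] <- list(id = id, type = "endothelial_cell",
                                      x = cell$voxel[1], y = cell$voxel[2],
                                      z = cell$voxel[3], state = cell$role,
                                      pred = cell$pred)
  }
  scene
}

scene_stats <- function(scene) {
  if (length(scene) == 0L) return(empty_stats())
  type <- vapply(scene, `[[`, character(1), "type")
  st <- vapply(scene, `[[`, character(1), "state")
  tab <- table(type, st)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, , drop = FALSE]
  df <- df[order(df$type, df$st), , drop = FALSE]
  data.frame(type = df$type, state = df$st, n = as.integer(df$Freq),
             row.names = NULL, stringsAsFactors = FALSE)
}

scene_step_document <- function(state, prev_scene) {
  cur <- live_scene(state)
  cur_ids <- sort(as.integer(names(cur)))
  prev_ids <- sort(as.integer(names(prev_scene)))
  messages <- list()
  for (id in cur_ids) {
    key <- as.character(id)
    c_ <- cur[[key]]
    p_ <- prev_scene[[key]]
    if (is.null(p_)) {
      messages[[length(messages) + 1L]] <-
        anim_message("create", id = id, type = c_$type,
                     voxel = c(c_$x, c_$y, c_$z), state = c_$state,
                     pred = c_$pred)
    } else if (p_$x != c_$x || p_$y != c_$y || p_$z != c_$z ||
               p_$state != c_$state || !identical(p_$pred, c_$pred)) {
      messages[[length(messages) + 1L]] <-
        anim_message("update", id = id, type = c_$type,
                     voxel = c(c_$x, c_$y, c_$z), state = c_$state,
                     pred = c_$pred)
    }
  }
  for (id in setdiff(prev_ids, cur_ids)) {
    messages[[length(messages) + 1L]] <- anim_message("delete", id = id)
  }
  if (length(state$pending_events)) {
    messages <- c(messages, state$pending_events)
  }
  doc <- encode_step(state$step, messages, scene_stats(cur))
  list(doc = doc, scene = cur)
}
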