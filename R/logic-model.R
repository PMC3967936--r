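# ---- Expression dialect -------------------------------------------------
#
# Conditions over component levels are written in a compact dialect:
#   Name      level >= 1
#   Name:k    level >= k
#   Name=k    level == k
#   & | ! ()  conjunction, disjunction, negation, grouping
# Conditions are translated once, at parse time, into R expressions that are
# evaluated against named lists of (equal-shaped) integer arrays, so the same
# rule code drives scalar states, whole state-space batches and grid matrices.

.dialect_atoms <- function(text) {
  # returns data.frame(name, op, level) of the atoms appearing in `text`
  m <- gregexpr("[A-Za-z_][A-Za-z0-9_]*\\s*(:\\s*[0-9]+|=\\s*[0-9]+)?", text, perl = TRUE)
  toks <- regmatches(text, m)[[1]]
  if (!length(toks)) {
    return(data.frame(name = character(), op = character(), level = integer()))
  }
  name <- sub("^([A-Za-z_][A-Za-z0-9_]*).*$", "\\1", toks)
  rest <- sub("^[A-Za-z_][A-Za-z0-9_]*\\s*", "", toks)
  op <- ifelse(rest == "", "ge", ifelse(substr(rest, 1, 1) == ":", "ge", "eq"))
  level <- ifelse(rest == "", 1L, as.integer(sub("^[:=]\\s*", "", rest)))
  data.frame(name = name, op = op, level = level, stringsAsFactors = FALSE)
}

.translate_condition <- function(text) {
  x <- text
  x <- gsub("([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*([0-9]+)", "(\\1>=\\2)", x, perl = TRUE)
  x <- gsub("([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([0-9]+)", "(\\1==\\2)", x, perl = TRUE)
  x <- gsub("([A-Za-z_][A-Za-z0-9_]*)(?![A-Za-z0-9_]|\\s*[>=])", "(\\1>=1)", x, perl = TRUE)
  ok <- tryCatch(str2lang(x), error = function(e) NULL)
  if (is.null(ok)) stop("malformed condition: '", text, "'", call. = FALSE)
  ok
}

.check_atoms <- function(text, comp_tab, where) {
  atoms <- .dialect_atoms(text)
  for (i in seq_len(nrow(atoms))) {
    nm <- atoms$name[i]
    j <- match(nm, comp_tab$name)
    if (is.na(j)) {
      stop(where, ": condition references undeclared component '", nm, "'",
           call. = FALSE)
    }
    lv <- atoms$level[i]
    mx <- comp_tab$max[j]
    lo <- if (atoms$op[i] == "eq") 0L else 1L
    if (lv < lo || lv > mx) {
      stop(where, ": level ", lv, " out of range 0..", mx, " for '", nm, "'",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

.parse_clauses <- function(raw, comp_tab, comp_name, max_level, where) {
  if (is.null(raw) || !length(raw)) {
    stop(where, ": empty clause list for '", comp_name, "'", call. = FALSE)
  }
  lapply(raw, function(cl) {
    if (is.null(cl$`if`) || is.null(cl$to)) {
      stop(where, ": each clause needs fields 'if' and 'to' ('", comp_name, "')",
           call. = FALSE)
    }
    to <- as.integer(cl$to)
    if (is.na(to) || to < 1L || to > max_level) {
      stop(where, ": clause target ", cl$to, " outside 1..", max_level,
           " for '", comp_name, "'", call. = FALSE)
    }
    .check_atoms(cl$`if`, comp_tab, where)
    list(cond = as.character(cl$`if`),
         expr = .translate_condition(cl$`if`),
         target = to,
         note = if (is.null(cl$note)) NA_character_ else as.character(cl$note))
  })
}

# ---- Model construction -------------------------------------------------

#' Parse a declarative logical-model file
#'
#' Models are plain-text YAML documents with four sections: `components`
#' (name, max level, input flag, optional update delay), `derived`
#' (instantaneous integration variables defined by clause lists), `rules`
#' (one ordered clause list per non-input component; the first clause whose
#' condition holds gives the target level, the implicit default target is 0)
#' and `priorities` (ordered classes; earlier classes update first within a
#' synchronous tick).
#'
#' @param text model-file content as a single string, or a character vector of
#'   lines.
#' @return an object of class `logical_model`.
#' @seealso [read_model()], [write_model()]
#' @export
parse_model <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  doc <- yaml::yaml.load(text)
  if (is.null(doc$components)) stop("model file has no 'components' section")

  comp_tab <- do.call(rbind, lapply(doc$components, function(cc) {
    if (is.null(cc$name) || is.null(cc$max)) {
      stop("every component needs 'name' and 'max'")
    }
    mx <- as.integer(cc$max)
    if (is.na(mx) || mx < 1L) stop("max level must be >= 1 for '", cc$name, "'")
    data.frame(name = as.character(cc$name), max = mx,
               input = isTRUE(cc$input),
               delay = if (is.null(cc$delay)) 0L else as.integer(cc$delay),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(comp_tab$name)) {
    stop("duplicate component name: ",
         comp_tab$name[duplicated(comp_tab$name)][1])
  }

  derived <- list()
  if (!is.null(doc$derived)) {
    for (dd in doc$derived) {
      if (is.null(dd$name) || is.null(dd$max)) {
        stop("every derived variable needs 'name' and 'max'")
      }
      if (dd$name %in% comp_tab$name) {
        stop("derived variable '", dd$name, "' clashes with a component name")
      }
      derived[[dd$name]] <- list(max = as.integer(dd$max), clauses = NULL,
                                 raw = dd$clauses)
    }
    # atoms of derived clauses may reference components and earlier deriveds
    ext_tab <- comp_tab
    for (nm in names(derived)) {
      ext_tab <- rbind(ext_tab, data.frame(
        name = nm, max = derived[[nm]]$max, input = FALSE, delay = 0L))
    }
    for (nm in names(derived)) {
      derived[[nm]]$clauses <- .parse_clauses(
        derived[[nm]]$raw, ext_tab, nm, derived[[nm]]$max,
        paste0("derived '", nm, "'"))
      derived[[nm]]$raw <- NULL
    }
  }

  # rule atoms may reference any component or derived variable
  full_tab <- comp_tab
  for (nm in names(derived)) {
    full_tab <- rbind(full_tab, data.frame(
      name = nm, max = derived[[nm]]$max, input = FALSE, delay = 0L))
  }

  rules <- list()
  non_inputs <- comp_tab$name[!comp_tab$input]
  for (nm in names(doc$rules)) {
    j <- match(nm, comp_tab$name)
    if (is.na(j)) stop("rule for undeclared component '", nm, "'")
    if (comp_tab$input[j]) stop("rule given for input component '", nm, "'")
    rules[[nm]] <- .parse_clauses(doc$rules[[nm]], full_tab, nm,
                                  comp_tab$max[j], paste0("rule '", nm, "'"))
  }
  missing <- setdiff(non_inputs, names(rules))
  if (length(missing)) {
    stop("missing rule for non-input component(s): ",
         paste(missing, collapse = ", "))
  }

  priorities <- doc$priorities
  if (is.null(priorities)) {
    priorities <- list(non_inputs)
  } else {
    priorities <- lapply(priorities, as.character)
    flat <- unlist(priorities)
    if (anyDuplicated(flat) ||
        length(setdiff(flat, non_inputs)) ||
        length(setdiff(non_inputs, flat))) {
      stop("priorities must partition exactly the non-input components")
    }
  }

  structure(list(name = if (is.null(doc$name)) "model" else doc$name,
                 schema = if (is.null(doc$schema)) 1L else as.integer(doc$schema),
                 components = comp_tab,
                 derived = derived,
                 rules = rules,
                 priorities = priorities),
            class = "logical_model")
}

#' Read a logical model from a file
#' @param path path to a model file (YAML).
#' @return a `logical_model`.
#' @export
read_model <- function(path) {
  parse_model(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Serialize a logical model back to its file format
#'
#' The parse/serialize round trip is lossless up to whitespace: parsing the
#' output of `write_model()` yields a model identical to the input.
#'
#' @param model a `logical_model`.
#' @param path optional output file; when `NULL` the YAML text is returned.
#' @export
write_model <- function(model, path = NULL) {
  ct <- model$components
  doc <- list(
    schema = model$schema,
    name = model$name,
    components = lapply(seq_len(nrow(ct)), function(i) {
      out <- list(name = ct$name[i], max = ct$max[i])
      if (ct$input[i]) out$input <- TRUE
      if (ct$delay[i] > 0L) out$delay <- ct$delay[i]
      out
    }),
    derived = if (length(model$derived)) {
      lapply(names(model$derived), function(nm) {
        d <- model$derived[[nm]]
        list(name = nm, max = d$max,
             clauses = lapply(d$clauses, .clause_out))
      })
    },
    rules = lapply(model$rules, function(cls) lapply(cls, .clause_out)),
    priorities = model$priorities
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  txt <- yaml::as.yaml(doc)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

.clause_out <- function(cl) {
  out <- list(`if` = cl$cond, to = cl$target)
  if (!is.na(cl$note)) out$note <- cl$note
  out
}

#' @export
print.logical_model <- function(x, ...) {
  ct <- x$components
  cat("Logical model '", x$name, "': ", nrow(ct), " components (",
      sum(ct$input), " inputs",
      if (length(x$derived)) paste0(", ", length(x$derived), " derived"),
      ")\n", sep = "")
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("  %-10s 0..%d%s%s\n", ct$name[i], ct$max[i],
                if (ct$input[i]) " [input]" else "",
                if (ct$delay[i] > 0) paste0(" [delay ", ct$delay[i], "]") else ""))
  }
  invisible(x)
}

# ---- Small accessors ----------------------------------------------------

model_inputs <- function(model) model$components$name[model$components$input]

model_internals <- function(model) model$components$name[!model$components$input]

component_max <- function(model, name) {
  j <- match(name, model$components$name)
  if (any(is.na(j))) {
    d <- model$derived[[name[is.na(j)][1]]]
    if (!is.null(d)) return(d$max)
    stop("unknown component '", name[is.na(j)][1], "'")
  }
  model$components$max[j]
}

delayed_components <- function(model) {
  model$components$name[!model$components$input & model$components$delay > 0L]
}
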