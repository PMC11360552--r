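# KEGG-style module definitions: parsing the step grammar, stepwise
# completeness against a KO set, and pathway classification (present /
# complete / AMG-targeted / AMG hot-spot).

# split s at top-level (outside parentheses) occurrences of any sep char
.splitTopLevel <- function(s, seps) {
  cs <- strsplit(s, "")[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(cs)) {
    ch <- cs[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at position ", i, " in: ", s, call. = FALSE)
    } else if (depth == 0L && ch %in% seps) cuts <- c(cuts, i)
  }
  if (depth != 0L) stop("unbalanced '(' in: ", s, call. = FALSE)
  if (!length(cuts)) return(s)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(cs))
  vapply(seq_along(starts), function(r) {
    if (starts[r] > ends[r]) ""
    else paste(cs[starts[r]:ends[r]], collapse = "")
  }, character(1))
}

.parseExpr <- function(s) {
  parts <- .splitTopLevel(s, ",")
  if (length(parts) > 1L)
    return(list(op = "OR", children = lapply(parts, .parseAnd)))
  .parseAnd(parts)
}

.parseAnd <- function(s) {
  parts <- .splitTopLevel(s, c("+", " "))
  parts <- parts[nzchar(parts)]
  if (length(parts) > 1L)
    return(list(op = "AND", children = lapply(parts, .parseMinus)))
  if (!length(parts)) stop("empty component in module definition")
  .parseMinus(parts)
}

.parseMinus <- function(s) {
  if (s == "--") return(list(op = "GAP"))
  parts <- .splitTopLevel(s, "-")
  if (length(parts) == 1L) return(.parseUnit(parts))
  if (parts[1] == "") {                  # leading '-': whole unit optional
    rest <- paste(parts[-1][nzchar(parts[-1])], collapse = "-")
    if (!nzchar(rest)) return(list(op = "GAP"))
    return(list(op = "OPT", child = .parseExpr(rest)))
  }
  children <- c(list(.parseUnit(parts[1])),
                lapply(parts[-1][nzchar(parts[-1])], function(p) {
                  list(op = "OPT", child = .parseUnit(p))
                }))
  if (length(children) == 1L) return(children[[1]])
  list(op = "AND", children = children)
}

.parseUnit <- function(s) {
  if (startsWith(s, "(") && endsWith(s, ")")) {
    inner <- substr(s, 2L, nchar(s) - 1L)
    # only strip if these parentheses actually match each other
    if (identical(.splitTopLevel(inner, character(0)), inner))
      return(.parseExpr(inner))
  }
  if (!grepl("^[A-Za-z0-9_.:]+$", s))
    stop("cannot parse module component: '", s, "'", call. = FALSE)
  list(op = "KO", ko = s)
}

.evalNode <- function(node, kos) {
  switch(node$op,
         KO = node$ko %in% kos,
         GAP = FALSE,
         OPT = NA,
         AND = {
           vals <- vapply(node$children, .evalNode, logical(1), kos = kos)
           vals <- vals[!is.na(vals)]
           if (!length(vals)) TRUE else all(vals)
         },
         OR = {
           vals <- vapply(node$children, .evalNode, logical(1), kos = kos)
           vals <- vals[!is.na(vals)]
           if (!length(vals)) FALSE else any(vals)
         },
         stop("unknown node op: ", node$op))
}

.deparseNode <- function(node) {
  switch(node$op,
         KO = node$ko,
         GAP = "--",
         OPT = paste0("-", .deparseNode(node$child)),
         AND = paste(vapply(node$children, function(ch) {
           if (ch$op == "OR") paste0("(", .deparseNode(ch), ")")
           else .deparseNode(ch)
         }, character(1)), collapse = "+"),
         OR = paste(vapply(node$children, .deparseNode, character(1)),
                    collapse = ","))
}

#' Parse a KEGG-style module definition
#'
#' Top-level space-separated tokens (outside parentheses) are the module's
#' steps; within a step `,` is OR, `+` (or a space inside parentheses) is
#' AND, a `-`-prefixed component is optional (excluded from satisfaction and,
#' for top-level tokens, from the step count), and `--` is a gap step that
#' counts in the denominator but is never satisfied. Unbalanced parentheses
#' raise a parse error with the offending position.
#'
#' @param module_id module identifier.
#' @param definition the definition string.
#' @return a [ModuleDefinition].
#' @examples
#' m <- parseModuleDefinition("M1", "(K1,K2) K3+K4")
#' nSteps(m)
#' @export
parseModuleDefinition <- function(module_id, definition) {
  if (!nzchar(trimws(definition))) stop("empty module definition")
  toks <- .splitTopLevel(trimws(definition), " ")
  toks <- toks[nzchar(toks)]
  steps <- list()
  skipped <- character(0)
  for (tok in toks) {
    if (startsWith(tok, "-") && tok != "--") {
      skipped <- c(skipped, tok)
      next
    }
    steps[[length(steps) + 1L]] <- .parseExpr(tok)
  }
  new("ModuleDefinition", module_id = module_id, definition = definition,
      steps = steps, skipped = skipped)
}

#' Render a parsed module definition back to a string
#'
#' The round-trip `parseModuleDefinition(unparseModuleDefinition(x))` yields
#' an equivalent expression (identical step satisfaction on every KO set).
#'
#' @param module a [ModuleDefinition].
#' @return a definition string.
#' @export
unparseModuleDefinition <- function(module) {
  stopifnot(is(module, "ModuleDefinition"))
  toks <- vapply(moduleSteps(module), function(st) {
    if (st$op %in% c("OR")) paste0("(", .deparseNode(st), ")")
    else .deparseNode(st)
  }, character(1))
  paste(c(toks, module@skipped), collapse = " ")
}

#' Stepwise completeness of a module for a KO set
#'
#' A step is satisfied iff its boolean tree evaluates true given
#' `present_kos` (optional components ignored; gap steps never satisfied).
#' Completeness is satisfied steps over total steps; the module is complete
#' at `completeness >= threshold`.
#'
#' @param module a [ModuleDefinition] (or a definition string, parsed with
#'   module id `"module"`).
#' @param present_kos character vector of present KO identifiers.
#' @param threshold completeness threshold (default 0.75).
#' @param source optional label (`"microbial"` / `"viral"`) carried into the
#'   result.
#' @return a list with `module_id`, `source`, `n_steps`, `n_satisfied`,
#'   `completeness`, `complete`.
#' @examples
#' m <- parseModuleDefinition("M1", "K1 K2 K3 K4")
#' stepwiseCompleteness(m, c("K1", "K2", "K3"))$completeness  # 0.75
#' @export
stepwiseCompleteness <- function(module, present_kos, threshold = 0.75,
                                 source = NA_character_) {
  if (is.character(module))
    module <- parseModuleDefinition("module", module)
  stopifnot(is(module, "ModuleDefinition"))
  steps <- moduleSteps(module)
  n <- length(steps)
  sat <- if (n) vapply(steps, .evalNode, logical(1), kos = present_kos)
         else logical(0)
  comp <- if (n) sum(sat) / n else 0
  list(module_id = module@module_id, source = source,
       n_steps = n, n_satisfied = sum(sat),
       completeness = comp, complete = comp >= threshold)
}

#' Classify pathways by microbial presence and AMG targeting
#'
#' For each module, reports whether it is present in the microbial fraction
#' (at least one step satisfied by microbial KOs), complete there
#' (completeness at or above `threshold`), AMG-targeted (microbial-present
#' and, in the default `"step"` mode, at least one step satisfied by the
#' pooled viral AMG KOs; in `"ko"` mode, any AMG KO occurring in the
#' definition), and an AMG hot-spot (AMG-targeted with viral completeness at
#' or above `threshold`). Hot-spot signals are community aggregates: AMG KOs
#' are pooled across all virus populations.
#'
#' @param modules a data.frame with `module_id` and `definition` columns, or
#'   a list of [ModuleDefinition] objects.
#' @param microbial_kos KOs present on microbial contigs.
#' @param viral_amg_kos KOs carried by catalog AMGs.
#' @param threshold completeness threshold (default 0.75).
#' @param targeted_mode `"step"` (default) or `"ko"`.
#' @return a data.frame (one row per module) with completeness columns and
#'   the four logical categories; counts are attached as
#'   `attr(x, "summary")`.
#' @export
classifyPathways <- function(modules, microbial_kos, viral_amg_kos,
                             threshold = 0.75,
                             targeted_mode = c("step", "ko")) {
  targeted_mode <- match.arg(targeted_mode)
  if (is.data.frame(modules)) {
    modules <- lapply(seq_len(nrow(modules)), function(i) {
      parseModuleDefinition(modules$module_id[i], modules$definition[i])
    })
  }
  rows <- lapply(modules, function(m) {
    mc <- stepwiseCompleteness(m, microbial_kos, threshold)
    vc <- stepwiseCompleteness(m, viral_amg_kos, threshold)
    present <- mc$n_satisfied >= 1L
    targeted <- if (targeted_mode == "step") present && vc$n_satisfied >= 1L
                else present && any(regmatches(
                  m@definition, gregexpr("[A-Za-z0-9_.:]+",
                                         m@definition))[[1]] %in%
                    viral_amg_kos)
    data.frame(module_id = m@module_id,
               n_steps = mc$n_steps,
               microbial_satisfied = mc$n_satisfied,
               microbial_completeness = mc$completeness,
               viral_satisfied = vc$n_satisfied,
               viral_completeness = vc$completeness,
               microbial_present = present,
               microbial_complete = present && mc$complete,
               amg_targeted = targeted,
               amg_hotspot = targeted && vc$complete,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(
    n_modules = nrow(out),
    n_microbial_present = sum(out$microbial_present),
    n_microbial_complete = sum(out$microbial_complete),
    n_amg_targeted = sum(out$amg_targeted),
    n_amg_hotspot = sum(out$amg_hotspot))
  out
}
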