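#' Construct a mass-action reaction network model
#'
#' The unit of work simulated by every parallel job: a set of chemical
#' species (in particle numbers), mass-action reactions, and named rate
#' parameters. Kinetics are restricted to mass action; each reaction's rate
#' constant is a reference into the parameter table, so a job document can
#' substitute parameter values without touching the network structure.
#'
#' @param species a data frame (or tibble) with columns `name` and
#'   `initial_amount` (non-negative, particle numbers), or a named numeric
#'   vector of initial amounts.
#' @param reactions a list of reactions, each a list with elements
#'   `reactants` (named integer vector: species name -> stoichiometry),
#'   `products` (same form), and `rate` (the name of a parameter holding the
#'   rate constant). Either side may be empty (`c()`) for source/sink
#'   reactions. An optional `name` element labels the reaction.
#' @param parameters named numeric vector of rate constants and any other
#'   model parameters.
#' @param volume positive real, arbitrary units. Defaults to 1; amounts are
#'   particle numbers throughout, so volume only matters to users who wish to
#'   interpret amounts as concentrations.
#' @param name optional model name.
#'
#' @return an object of class `rn_model`.
#' @examples
#' m <- rn_model(
#'   species    = c(A = 100),
#'   reactions  = list(list(reactants = c(A = 1), products = c(), rate = "k")),
#'   parameters = c(k = 1)
#' )
#' m
#' @export
rn_model <- function(species, reactions, parameters, volume = 1, name = "model") {
  if (is.numeric(species) && !is.null(names(species))) {
    species <- tibble::tibble(name = names(species), initial_amount = unname(species))
  }
  species <- tibble::as_tibble(species)
  stopifnot(all(c("name", "initial_amount") %in% names(species)))
  reactions <- lapply(reactions, function(r) {
    r$reactants <- canon_stoich(r$reactants)
    r$products  <- canon_stoich(r$products)
    r
  })
  m <- structure(
    list(species = species, reactions = reactions,
         parameters = parameters, volume = volume, name = name),
    class = "rn_model"
  )
  validate_rn_model(m)
  m
}

canon_stoich <- function(x) {
  if (is.null(x) || length(x) == 0) return(stats::setNames(integer(0), character(0)))
  stats::setNames(as.integer(x), names(x))
}

#' Validate a reaction network model
#'
#' Checks the structural invariants: unique species and parameter names,
#' every rate-constant reference resolving to a parameter, non-negative
#' integer stoichiometries, non-negative initial amounts, positive volume.
#'
#' @param m an `rn_model`.
#' @return `m`, invisibly, or an error describing the first violation.
#' @export
validate_rn_model <- function(m) {
  stopifnot(inherits(m, "rn_model"))
  sp <- m$species$name
  if (anyDuplicated(sp)) stop("duplicate species names: ",
                              paste(unique(sp[duplicated(sp)]), collapse = ", "))
  if (anyDuplicated(names(m$parameters)))
    stop("duplicate parameter names")
  if (any(!is.finite(m$species$initial_amount)) || any(m$species$initial_amount < 0))
    stop("initial amounts must be finite and >= 0")
  if (!is.numeric(m$volume) || length(m$volume) != 1 || m$volume <= 0)
    stop("volume must be a positive real")
  for (i in seq_along(m$reactions)) {
    r <- m$reactions[[i]]
    if (!r$rate %in% names(m$parameters))
      stop("reaction ", i, ": rate constant '", r$rate, "' is not a model parameter")
    st <- c(r$reactants, r$products)
    if (length(st)) {
      if (any(!names(st) %in% sp))
        stop("reaction ", i, ": unknown species ",
             paste(setdiff(names(st), sp), collapse = ", "))
      if (any(st < 0)) stop("reaction ", i, ": negative stoichiometry")
    }
  }
  invisible(m)
}

#' @export
print.rn_model <- function(x, ...) {
  cat("<rn_model> ", x$name, ": ", nrow(x$species), " species, ",
      length(x$reactions), " reactions, ", length(x$parameters),
      " parameters\n", sep = "")
  for (r in x$reactions) {
    cat("  ", format_side(r$reactants), " -> ", format_side(r$products),
        "  ; ", r$rate, " = ", x$parameters[[r$rate]], "\n", sep = "")
  }
  invisible(x)
}

format_side <- function(st) {
  if (!length(st)) return("0")
  paste(ifelse(st == 1L, names(st), paste0(st, " ", names(st))), collapse = " + ")
}

#' Substitute parameter values into a model
#'
#' Returns a copy of the model with the named parameters replaced; used to
#' embed per-grid-point values into scan job documents and to export the
#' winning parameter set of an optimization as a runnable model document.
#'
#' @param m an `rn_model`.
#' @param values named numeric vector; names must be existing parameters.
#' @return the updated `rn_model`.
#' @export
set_parameters <- function(m, values) {
  unknown <- setdiff(names(values), names(m$parameters))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  m$parameters[names(values)] <- values
  validate_rn_model(m)
  m
}

# ---- native model document (structured text) --------------------------------

#' Write a model as a native structured-text document
#'
#' The native dialect is a small sectioned text format: `[species]`,
#' `[parameters]`, `[reactions]` (lines like `decay: A -> 0 ; k`), and
#' `[volume]`. It exists so each parallel job can carry a self-contained,
#' human-readable model file.
#'
#' @param m an `rn_model`.
#' @param path file to write. With `path = NULL` the lines are returned
#'   instead of written.
#' @return `path` invisibly (or the character vector of lines).
#' @export
write_model_doc <- function(m, path = NULL) {
  validate_rn_model(m)
  lines <- c(
    paste("# model", m$name),
    "[species]",
    sprintf("%s = %s", m$species$name, format_num(m$species$initial_amount)),
    "[parameters]",
    sprintf("%s = %s", names(m$parameters), format_num(unname(m$parameters))),
    "[reactions]",
    vapply(seq_along(m$reactions), function(i) {
      r <- m$reactions[[i]]
      nm <- if (!is.null(r$name)) r$name else paste0("r", i)
      paste0(nm, ": ", format_side(r$reactants), " -> ",
             format_side(r$products), " ; ", r$rate)
    }, character(1)),
    "[volume]",
    format_num(m$volume)
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

#' Read a native model document
#'
#' @param path file to read, or a character vector of lines.
#' @return an `rn_model`.
#' @export
read_model_doc <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  name <- "model"
  if (length(lines) && startsWith(lines[1], "# model"))
    name <- trimws(sub("^# model", "", lines[1]))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  known <- c("[species]", "[parameters]", "[reactions]", "[volume]")
  if (!"[species]" %in% lines ||
      any(grepl("^\\[", lines) & !lines %in% known))
    stop("malformed model document: expected [species]/[parameters]/[reactions]/[volume] sections")
  sec <- cumsum(grepl("^\\[", lines))
  headers <- sub("\\]$", "", sub("^\\[", "", lines[grepl("^\\[", lines)]))
  body <- split(lines[!grepl("^\\[", lines)], sec[!grepl("^\\[", lines)])
  names(body) <- headers[as.integer(names(body))]
  kv <- function(x) {
    parts <- strsplit(x, "=", fixed = TRUE)
    stats::setNames(vapply(parts, function(p) as.numeric(trimws(p[2])), 1),
                    vapply(parts, function(p) trimws(p[1]), ""))
  }
  sp  <- kv(body$species %||% character(0))
  par <- kv(body$parameters %||% character(0))
  reactions <- lapply(body$reactions %||% character(0), parse_reaction_line)
  vol <- if (!is.null(body$volume)) as.numeric(body$volume[1]) else 1
  rn_model(species = sp, reactions = reactions, parameters = par,
           volume = vol, name = name)
}

parse_reaction_line <- function(line) {
  nm <- NULL
  if (grepl(":", line, fixed = TRUE)) {
    nm <- trimws(sub(":.*$", "", line))
    line <- sub("^[^:]*:", "", line)
  }
  halves <- strsplit(line, ";", fixed = TRUE)[[1]]
  if (length(halves) != 2) stop("malformed reaction line: ", line)
  rate <- trimws(halves[2])
  sides <- strsplit(halves[1], "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop("malformed reaction line: ", line)
  list(name = nm, reactants = parse_side(sides[1]),
       products = parse_side(sides[2]), rate = rate)
}

parse_side <- function(s) {
  s <- trimws(s)
  if (s == "" || s == "0") return(c())
  terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  st <- integer(0)
  for (t in terms) {
    mm <- regmatches(t, regexec("^([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_]*)$", t))[[1]]
    if (length(mm) == 0) stop("malformed species term: ", t)
    coef <- if (nzchar(mm[2])) as.integer(mm[2]) else 1L
    st[mm[3]] <- (if (mm[3] %in% names(st)) st[[mm[3]]] else 0L) + coef
  }
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a
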