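#' Construct a validated long-format choice dataset
#'
#' One row is one alternative within one choice task. Every
#' \code{(person_id, task_id)} group must contain at least two available
#' alternatives and exactly one chosen row among the available ones;
#' attribute values must be finite. Identifiers are opaque labels ordered
#' by first appearance, so enumeration output is reproducible.
#'
#' @param df data.frame holding the panel in long format.
#' @param person,task,alt names of the identifier columns in \code{df}.
#' @param choice name of the 0/1 (or logical) chosen-indicator column.
#' @param available optional name of a 0/1 availability column; if
#'   \code{NULL} all alternatives are treated as available.
#' @param attributes character vector of attribute column names; defaults
#'   to every remaining numeric column.
#' @param alt_groups optional named list mapping group labels (for example
#'   \code{branded}) to vectors of alternative labels; used by sample
#'   enumeration.
#' @return An object of class \code{choice_data}: a data.frame with
#'   standardized columns \code{person_id}, \code{task_id}, \code{alt_id},
#'   \code{available}, \code{chosen} followed by the attribute columns.
#' @export
choice_data <- function(df, person = "person_id", task = "task_id",
                        alt = "alt_id", choice = "chosen",
                        available = NULL, attributes = NULL,
                        alt_groups = NULL) {
  df <- as.data.frame(df)
  needed <- c(person, task, alt, choice, available)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    person_id = as.character(df[[person]]),
    task_id = as.character(df[[task]]),
    alt_id = as.character(df[[alt]]),
    available = if (is.null(available)) TRUE else as.logical(df[[available]]),
    chosen = as.logical(df[[choice]]),
    stringsAsFactors = FALSE
  )
  if (is.null(attributes)) {
    rest <- setdiff(names(df), needed)
    attributes <- rest[vapply(df[rest], is.numeric, logical(1))]
  }
  for (a in attributes) {
    if (!a %in% names(df)) stop("attribute column not found: ", a, call. = FALSE)
    out[[a]] <- as.numeric(df[[a]])
  }
  # carry categorical columns along untouched so they can be dummy coded
  categorical <- setdiff(names(df), c(needed, attributes))
  categorical <- categorical[vapply(df[categorical],
                                    function(v) is.character(v) || is.factor(v),
                                    logical(1))]
  for (a in categorical) out[[a]] <- as.character(df[[a]])
  # order by first appearance of person, then task within person
  pkey <- match(out$person_id, unique(out$person_id))
  tkey <- match(paste(out$person_id, out$task_id, sep = "\r"),
                unique(paste(out$person_id, out$task_id, sep = "\r")))
  out <- out[order(pkey, tkey), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attributes") <- attributes
  attr(out, "alt_groups") <- alt_groups
  class(out) <- c("choice_data", "data.frame")
  validate_choice_data(out)
  out
}

#' @rdname choice_data
#' @param x a \code{choice_data} object.
#' @export
validate_choice_data <- function(x) {
  attrs <- attr(x, "attributes")
  for (a in attrs) {
    if (!all(is.finite(x[[a]]))) {
      stop("non-finite values in attribute '", a, "'", call. = FALSE)
    }
  }
  if (any(x$chosen & !x$available)) {
    stop("a chosen alternative is marked unavailable", call. = FALSE)
  }
  key <- paste(x$person_id, x$task_id, sep = "\r")
  n_avail <- tapply(x$available, key, sum)
  if (any(n_avail < 2)) {
    bad <- names(n_avail)[n_avail < 2][1]
    stop("task ", sub("\r", "/", bad), " has fewer than 2 available alternatives",
         call. = FALSE)
  }
  n_chosen <- tapply(x$chosen & x$available, key, sum)
  if (any(n_chosen != 1)) {
    bad <- names(n_chosen)[n_chosen != 1][1]
    stop("task ", sub("\r", "/", bad),
         " must have exactly one chosen available alternative (found ",
         n_chosen[match(bad, names(n_chosen))], ")", call. = FALSE)
  }
  invisible(x)
}

#' Read a long-format choice panel from CSV
#'
#' @param path CSV file path.
#' @param column_map named list mapping the roles \code{person}, \code{task},
#'   \code{alt}, \code{choice} (and optionally \code{available}) to column
#'   names in the file.
#' @param ... passed on to [choice_data()].
#' @return A validated \code{choice_data} object.
#' @export
read_choice_data <- function(path, column_map = list(), ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  args <- c(list(df = df), column_map, list(...))
  do.call(choice_data, args)
}

#' Write a choice panel to CSV
#'
#' Round-trips through [read_choice_data()] with the default column map.
#'
#' @param x a \code{choice_data} object.
#' @param path output file path.
#' @export
write_choice_data <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Dummy code a categorical attribute
#'
#' Replaces a categorical column with one 0/1 indicator per non-reference
#' level, named \code{<attribute>_<level>}; the reference level maps to all
#' zeros. Attribute levels in choice experiments are conventionally dummy
#' coded except for continuous attributes such as price.
#'
#' @param data a \code{choice_data} object (or plain data.frame).
#' @param attribute name of the categorical column.
#' @param reference_level the level absorbed into the reference.
#' @return The dataset with the categorical column replaced by indicators.
#' @export
dummy_code <- function(data, attribute, reference_level) {
  if (!attribute %in% names(data)) {
    stop("unknown attribute: ", attribute, call. = FALSE)
  }
  vals <- as.character(data[[attribute]])
  levels_all <- unique(vals)
  if (!reference_level %in% levels_all) {
    stop("unknown reference level '", reference_level, "' for attribute '",
         attribute, "'", call. = FALSE)
  }
  keep <- setdiff(levels_all, reference_level)
  old_attrs <- attr(data, "attributes")
  for (lev in keep) {
    data[[paste(attribute, lev, sep = "_")]] <- as.numeric(vals == lev)
  }
  data[[attribute]] <- NULL
  if (!is.null(old_attrs)) {
    attr(data, "attributes") <- c(setdiff(old_attrs, attribute),
                                  paste(attribute, keep, sep = "_"))
  }
  data
}

#' Construct a person-level binary-outcome panel
#'
#' Holds two binary outcomes per person (cigarette use and e-cigarette use
#' in the motivating application) plus person-level covariates, for the
#' correlated-error revealed-preference logit.
#'
#' @param df data.frame with one row per person.
#' @param person,cig,ecig column names for the identifier and the two 0/1
#'   outcomes.
#' @param covariates character vector of covariate column names (finite
#'   numeric); defaults to the remaining numeric columns.
#' @return An object of class \code{binary_panel}.
#' @export
binary_panel <- function(df, person = "person_id", cig = "cig", ecig = "ecig",
                         covariates = NULL) {
  df <- as.data.frame(df)
  for (col in c(person, cig, ecig)) {
    if (!col %in% names(df)) stop("missing column: ", col, call. = FALSE)
  }
  out <- data.frame(
    person_id = as.character(df[[person]]),
    cig = as.integer(df[[cig]]),
    ecig = as.integer(df[[ecig]]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$person_id)) {
    stop("binary panel must have one row per person", call. = FALSE)
  }
  if (!all(out$cig %in% 0:1) || !all(out$ecig %in% 0:1)) {
    stop("outcomes must be 0/1", call. = FALSE)
  }
  if (is.null(covariates)) {
    rest <- setdiff(names(df), c(person, cig, ecig))
    covariates <- rest[vapply(df[rest], is.numeric, logical(1))]
  }
  for (z in covariates) {
    v <- as.numeric(df[[z]])
    if (!all(is.finite(v))) stop("non-finite covariate: ", z, call. = FALSE)
    out[[z]] <- v
  }
  attr(out, "covariates") <- covariates
  class(out) <- c("binary_panel", "data.frame")
  out
}

#' @rdname binary_panel
#' @param path CSV file path.
#' @param column_map named list with entries \code{person}, \code{cig},
#'   \code{ecig}.
#' @export
read_binary_panel <- function(path, column_map = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  do.call(binary_panel, c(list(df = df), column_map))
}

#' @rdname binary_panel
#' @param x a \code{binary_panel} object.
#' @export
write_binary_panel <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
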