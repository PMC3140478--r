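#' Construct and validate a group roster
#'
#' A roster lists the individuals of one or more social groups together
#' with the attributes used downstream: sex, age class, experimentally
#' assigned cooperation class (the two-member "small" class operates one
#' feeder colour, everyone else forms the "large" class), matriline and
#' sibling set. Infants are excluded from all analyses; rows flagged as
#' infants are dropped with a message.
#'
#' @param x a data.frame with columns \code{id}, \code{sex} (\code{"M"} or
#'   \code{"F"}), \code{age_class} (\code{"adult"}, \code{"juvenile"} or
#'   \code{"infant"}), \code{coop_class} (\code{"small"} or \code{"large"}),
#'   and optionally \code{matriline}, \code{siblings} (semicolon-separated
#'   ids) and \code{group}.
#' @return a validated \code{vnet_roster} data.frame.
#' @export
as_roster <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("id", "sex", "age_class", "coop_class")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("roster is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x$id <- as.character(x$id)
  if (anyDuplicated(x$id)) {
    stop("duplicated individual ids in roster: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  }
  if (any(x$age_class == "infant")) {
    message("dropping ", sum(x$age_class == "infant"),
            " infant(s) from roster (excluded from all analyses)")
    x <- x[x$age_class != "infant", , drop = FALSE]
  }
  bad_sex <- !x$sex %in% c("M", "F")
  if (any(bad_sex)) stop("invalid sex value(s): ",
                         paste(unique(x$sex[bad_sex]), collapse = ", "))
  bad_age <- !x$age_class %in% c("adult", "juvenile")
  if (any(bad_age)) stop("invalid age_class value(s): ",
                         paste(unique(x$age_class[bad_age]), collapse = ", "))
  bad_cc <- !x$coop_class %in% c("small", "large")
  if (any(bad_cc)) stop("invalid coop_class value(s): ",
                        paste(unique(x$coop_class[bad_cc]), collapse = ", "))
  if (is.null(x$matriline)) x$matriline <- NA_character_
  if (is.null(x$siblings)) x$siblings <- ""
  x$siblings[is.na(x$siblings)] <- ""
  if (is.null(x$group)) x$group <- "group1"
  rownames(x) <- NULL
  class(x) <- c("vnet_roster", "data.frame")
  x
}

#' Read a roster from CSV
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return a \code{vnet_roster} data.frame, see [as_roster()].
#' @export
read_roster <- function(path) {
  as_roster(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a roster to CSV
#'
#' @param roster a \code{vnet_roster}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(as.data.frame(roster), path, row.names = FALSE)
  invisible(path)
}

#' Sibling sets of a roster
#'
#' @param roster a \code{vnet_roster}.
#' @return a named list of character vectors, one per individual.
#' @export
sibling_sets <- function(roster) {
  out <- lapply(roster$siblings, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  names(out) <- roster$id
  out
}

#' @export
print.vnet_roster <- function(x, ...) {
  cat("<roster> ", nrow(x), " individuals, ",
      length(unique(x$group)), " group(s); small class: ",
      paste(x$id[x$coop_class == "small"], collapse = ", "), "\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
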