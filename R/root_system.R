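#' Default genus to rooting-system lookup
#'
#' Terrestrial orchid genera of central Europe classified by the morphology
#' of their underground organs: \code{rhizomatous} (the ancestral state,
#' mostly forest species), \code{intermediate} (root tubers intermediate
#' between rhizomes and true tubers) and \code{tuberous} (the most derived
#' state, mostly open-habitat species). The table partitions 23 genera into
#' groups of 11, 4 and 8.
#'
#' @return A data frame with columns \code{genus} and \code{group}
#'   (factor with levels \code{rhizomatous}, \code{intermediate},
#'   \code{tuberous}).
#' @seealso [classify_root_system()]
#' @export
#' @examples
#' lk <- root_system_lookup()
#' table(lk$group)
root_system_lookup <- function() {
  rhizomatous <- c("Cephalanthera", "Corallorhiza", "Cypripedium",
                   "Epipactis", "Epipogium", "Goodyera", "Hammarbya",
                   "Limodorum", "Liparis", "Malaxis", "Neottia")
  intermediate <- c("Dactylorhiza", "Gymnadenia", "Platanthera",
                    "Pseudorchis")
  tuberous <- c("Anacamptis", "Herminium", "Himantoglossum", "Neotinea",
                "Ophrys", "Orchis", "Spiranthes", "Traunsteinera")
  data.frame(
    genus = c(rhizomatous, intermediate, tuberous),
    group = factor(
      rep(root_system_groups(),
          c(length(rhizomatous), length(intermediate), length(tuberous))),
      levels = root_system_groups()
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname root_system_lookup
#' @export
root_system_groups <- function() {
  c("rhizomatous", "intermediate", "tuberous")
}

validate_lookup <- function(lookup) {
  stopifnot(is.data.frame(lookup),
            all(c("genus", "group") %in% names(lookup)))
  if (anyDuplicated(lookup$genus)) {
    stop("duplicated genus in rooting-system lookup: ",
         paste(unique(lookup$genus[duplicated(lookup$genus)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(as.character(lookup$group)), root_system_groups())
  if (length(bad)) {
    stop("unknown rooting-system group(s) in lookup: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(lookup)
}

#' Classify a genus by its rooting system
#'
#' Pure lookup of the rooting-system group for one or more genera. Unknown
#' genera raise a condition of class \code{altiniche_unclassified_genus} so
#' callers can decide whether to abort or skip the offending records.
#'
#' @param genus Character vector of genus names.
#' @param lookup Lookup table as returned by [root_system_lookup()] or read
#'   with [read_lookup()].
#' @return Character vector of groups, same length as \code{genus}.
#' @export
#' @examples
#' classify_root_system("Epipactis")   # "rhizomatous"
#' classify_root_system("Dactylorhiza") # "intermediate"
#' classify_root_system("Ophrys")      # "tuberous"
classify_root_system <- function(genus, lookup = root_system_lookup()) {
  stopifnot(is.character(genus), all(nzchar(genus)))
  validate_lookup(lookup)
  idx <- match(genus, lookup$genus)
  if (anyNA(idx)) {
    unknown <- unique(genus[is.na(idx)])
    stop(structure(
      class = c("altiniche_unclassified_genus", "error", "condition"),
      list(message = paste0("genus not in rooting-system lookup: ",
                            paste(unknown, collapse = ", ")),
           call = sys.call(-1), genera = unknown)
    ))
  }
  as.character(lookup$group[idx])
}

#' Read a genus lookup table from CSV or YAML
#'
#' The CSV form has columns \code{genus,group}; the YAML form maps each group
#' name to a list of genera.
#'
#' @param path File path; format chosen by extension (.yaml/.yml vs anything
#'   else, parsed as CSV).
#' @return A validated lookup data frame.
#' @export
read_lookup <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    spec <- yaml::read_yaml(path)
    lookup <- data.frame(
      genus = unlist(spec, use.names = FALSE),
      group = rep(names(spec), lengths(spec)),
      stringsAsFactors = FALSE
    )
  } else {
    lookup <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  lookup$group <- factor(lookup$group, levels = root_system_groups())
  validate_lookup(lookup)
  lookup
}
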