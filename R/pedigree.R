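#' Construct a pedigree
#'
#' A pedigree is a data frame of individuals with family structure, sex and
#' affection status. Founders have both parent ids absent (`NA`). The graph
#' implied by the parent links must be acyclic and all parent references must
#' resolve to members of the same family.
#'
#' @param individual_id character vector of unique member ids.
#' @param father_id,mother_id character vectors of parent ids; `NA` (or `"0"`)
#'   when the parent is not in the pedigree. Both-absent marks a founder.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param affection `"affected"`, `"unaffected"` or `"unknown"`. Under the
#'   dominant model, amnestic-MCI-like prodromal cases should be coded
#'   `"affected"`; individuals of uncertain status `"unknown"` (they are
#'   always uninformative for segregation).
#' @param family_id single family id (recycled).
#' @return An object of class `pedigree`: a data frame with columns
#'   `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`,
#'   `affection`, in the order given.
#' @seealso [read_ped()], [cosegregation_check()]
#' @examples
#' trio <- pedigree(
#'   individual_id = c("F", "M", "C"),
#'   father_id     = c(NA, NA, "F"),
#'   mother_id     = c(NA, NA, "M"),
#'   sex           = c("male", "female", "female"),
#'   affection     = c("affected", "unaffected", "affected")
#' )
#' summary(trio)
#' @export
pedigree <- function(individual_id, father_id = NA_character_,
                     mother_id = NA_character_, sex = "unknown",
                     affection = "unknown", family_id = "FAM1") {
  n <- length(individual_id)
  ped <- data.frame(
    family_id     = rep_len(as.character(family_id), n),
    individual_id = as.character(individual_id),
    father_id     = rep_len(as.character(father_id), n),
    mother_id     = rep_len(as.character(mother_id), n),
    sex           = rep_len(as.character(sex), n),
    affection     = rep_len(as.character(affection), n),
    stringsAsFactors = FALSE
  )
  ped$father_id[ped$father_id %in% c("0", "")] <- NA_character_
  ped$mother_id[ped$mother_id %in% c("0", "")] <- NA_character_
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree invariants
#'
#' Checks id uniqueness, the controlled vocabularies for sex and affection,
#' that parent references resolve within the family, that at least one founder
#' exists, and that no individual is its own ancestor.
#'
#' @param ped a [pedigree()].
#' @return `ped`, invisibly, if valid; otherwise an error.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  if (nrow(ped) == 0L) stop("pedigree has no records")
  if (anyDuplicated(ped$individual_id)) {
    dup <- unique(ped$individual_id[duplicated(ped$individual_id)])
    stop("duplicate individual id(s): ", paste(dup, collapse = ", "))
  }
  if (!all(ped$sex %in% c("male", "female", "unknown"))) {
    stop("sex must be one of 'male', 'female', 'unknown'")
  }
  if (!all(ped$affection %in% c("affected", "unaffected", "unknown"))) {
    stop("affection must be one of 'affected', 'unaffected', 'unknown'")
  }
  for (col in c("father_id", "mother_id")) {
    ref <- ped[[col]]
    bad <- !is.na(ref) & !(ref %in% ped$individual_id)
    if (any(bad)) {
      stop("parent id(s) not in pedigree: ",
           paste(unique(ref[bad]), collapse = ", "))
    }
  }
  founder <- is.na(ped$father_id) & is.na(ped$mother_id)
  if (!any(founder)) stop("pedigree has no founder")
  # cycle check: peel founders repeatedly; leftovers lie on a cycle
  placed <- founder
  repeat {
    ok_parent <- function(p) is.na(p) | placed[match(p, ped$individual_id)]
    newly <- !placed & ok_parent(ped$father_id) & ok_parent(ped$mother_id)
    if (!any(newly)) break
    placed <- placed | newly
  }
  if (!all(placed)) {
    stop("pedigree contains a cycle involving: ",
         paste(ped$individual_id[!placed], collapse = ", "))
  }
  invisible(ped)
}

#' Read a 6-column PED file
#'
#' Parses the standard whitespace-delimited PED pedigree format: one row per
#' individual with columns family id, individual id, father id, mother id,
#' sex (1 = male, 2 = female, other = unknown) and phenotype
#' (1 = unaffected, 2 = affected, 0 or -9 = unknown). `"0"` parent ids mean
#' the parent is absent. File order is preserved.
#'
#' @param file path to a PED file, or a character vector of its lines.
#' @return A validated [pedigree()].
#' @examples
#' ped_file <- system.file("extdata", "family_wgs7.ped", package = "pedprio")
#' ped <- read_ped(ped_file)
#' summary(ped)
#' @export
read_ped <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("PED parse error: no records")
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("PED parse error: malformed line ", which(nf < 6L)[1L],
         " (expected 6 whitespace-delimited columns, got ", nf[nf < 6L][1L], ")")
  }
  m <- t(vapply(fields, function(x) x[1:6], character(6)))
  sex <- c("1" = "male", "2" = "female")[m[, 5L]]
  sex[is.na(sex)] <- "unknown"
  aff <- c("1" = "unaffected", "2" = "affected")[m[, 6L]]
  aff[is.na(aff)] <- "unknown"
  pedigree(
    individual_id = m[, 2L], father_id = m[, 3L], mother_id = m[, 4L],
    sex = sex, affection = aff, family_id = m[, 1L]
  )
}

#' Write a pedigree to a 6-column PED file
#'
#' @param ped a [pedigree()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_ped <- function(ped, file) {
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  aff <- c(unaffected = "1", affected = "2", unknown = "0")[ped$affection]
  fa <- ifelse(is.na(ped$father_id), "0", ped$father_id)
  mo <- ifelse(is.na(ped$mother_id), "0", ped$mother_id)
  writeLines(paste(ped$family_id, ped$individual_id, fa, mo, sex, aff,
                   sep = "\t"), file)
  invisible(file)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree '", x$family_id[1L], "': ", nrow(x), " members (",
      sum(x$affection == "affected"), " affected, ",
      sum(x$affection == "unaffected"), " unaffected, ",
      sum(x$affection == "unknown"), " unknown)\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  founders <- is.na(object$father_id) & is.na(object$mother_id)
  out <- list(
    family_id  = object$family_id[1L],
    n_members  = nrow(object),
    n_affected = sum(object$affection == "affected"),
    n_unaffected = sum(object$affection == "unaffected"),
    n_unknown  = sum(object$affection == "unknown"),
    n_founders = sum(founders)
  )
  class(out) <- "summary.pedigree"
  out
}

#' @export
print.summary.pedigree <- function(x, ...) {
  cat("Pedigree", x$family_id, "-", x$n_members, "members:",
      x$n_affected, "affected,", x$n_unaffected, "unaffected,",
      x$n_unknown, "unknown affection;", x$n_founders, "founder(s)\n")
  invisible(x)
}

#' Per-individual genotype/phenotype consistency under a dominant model
#'
#' Under the autosomal-dominant model an affected individual is expected to
#' carry at least one alternate allele and an unaffected individual none.
#' Individuals with unknown affection or missing genotype are uninformative.
#'
#' @param affection `"affected"`, `"unaffected"` or `"unknown"` (vectorized).
#' @param allele_count alternate-allele copies: 0, 1, 2, or `NA` for missing
#'   (vectorized).
#' @param model inheritance model; only `"dominant"` is supported.
#' @return Character vector with values `"consistent"`, `"violation"` or
#'   `"uninformative"`.
#' @examples
#' check_individual_consistency("affected", 1)    # consistent
#' check_individual_consistency("unaffected", 1)  # violation
#' check_individual_consistency("unknown", 1)     # uninformative
#' @export
check_individual_consistency <- function(affection, allele_count,
                                         model = "dominant") {
  if (!identical(model, "dominant")) {
    stop("unsupported inheritance model: ", model)
  }
  n <- max(length(affection), length(allele_count))
  affection <- rep_len(affection, n)
  allele_count <- rep_len(allele_count, n)
  out <- rep("uninformative", n)
  informative <- affection %in% c("affected", "unaffected") & !is.na(allele_count)
  carrier <- !is.na(allele_count) & allele_count >= 1L
  ok <- (affection == "affected" & carrier) |
        (affection == "unaffected" & !carrier)
  out[informative & ok] <- "consistent"
  out[informative & !ok] <- "violation"
  out
}

#' Autosomal-dominant co-segregation check
#'
#' Aggregates the per-individual dominant consistency rule over a pedigree:
#' every informative member (non-missing genotype, known affection) must fit
#' the pattern affected = carrier, unaffected = non-carrier. Members absent
#' from the genotype map are uninformative. The variant is called segregating
#' when there are no violations and at least `min_informative` informative
#' members.
#'
#' @param ped a [pedigree()].
#' @param genotypes named vector of alternate-allele counts (0/1/2, `NA`
#'   missing); names are individual ids and must be a subset of the pedigree
#'   members.
#' @param model inheritance model (`"dominant"`).
#' @param min_informative minimum informative members required to call
#'   segregation (default 2: at least one affected and one unaffected member
#'   can then be represented).
#' @return An object of class `segregation_result`: list with
#'   `n_informative`, `n_consistent`, `n_violations`, `violating_ids`,
#'   `segregates`.
#' @examples
#' ped <- read_ped(system.file("extdata", "family_wgs7.ped", package = "pedprio"))
#' g <- c("II-1" = 1, "III-2" = 1, "III-3" = 1, "III-4" = 1, "III-5" = 1,
#'        "II-2" = 0, "III-8" = 0)
#' cosegregation_check(ped, g)
#' @export
cosegregation_check <- function(ped, genotypes, model = "dominant",
                                min_informative = 2L) {
  stopifnot(inherits(ped, "pedigree"))
  ids <- names(genotypes)
  if (length(genotypes) && is.null(ids)) {
    stop("genotypes must be a named vector of individual ids")
  }
  unknown <- setdiff(ids, ped$individual_id)
  if (length(unknown)) {
    stop("genotype given for unknown individual(s): ",
         paste(unknown, collapse = ", "))
  }
  g <- genotypes[match(ped$individual_id, ids)]  # NA when absent from the map
  status <- check_individual_consistency(ped$affection, as.numeric(g), model)
  res <- list(
    n_informative = sum(status != "uninformative"),
    n_consistent  = sum(status == "consistent"),
    n_violations  = sum(status == "violation"),
    violating_ids = ped$individual_id[status == "violation"],
    segregates    = sum(status == "violation") == 0L &&
                    sum(status != "uninformative") >= min_informative
  )
  class(res) <- "segregation_result"
  res
}

#' @export
print.segregation_result <- function(x, ...) {
  cat("Co-segregation:", if (x$segregates) "SEGREGATES" else "does not segregate",
      sprintf("(%d informative: %d consistent, %d violation%s)\n",
              x$n_informative, x$n_consistent, x$n_violations,
              if (x$n_violations == 1L) "" else "s"))
  if (length(x$violating_ids)) {
    cat("  violating:", paste(x$violating_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count carriers in a genotype map
#'
#' A carrier holds at least one alternate allele; missing genotypes are
#' excluded.
#'
#' @inheritParams cosegregation_check
#' @return Integer count.
#' @export
count_carriers <- function(genotypes) {
  sum(!is.na(genotypes) & genotypes >= 1L)
}
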