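#' Define one predictor criterion
#'
#' A criterion turns one in-silico tool's output into a satisfied /
#' unsatisfied / missing verdict. Numeric kinds use strict inequalities
#' (boundary values are unsatisfied); label kinds test membership of the
#' configured damaging vocabulary. A missing annotation is never counted and
#' is flagged in the score breakdown.
#'
#' @param tool tool name (unique within a registry); must match an
#'   annotation-table column.
#' @param kind `"numeric_below"`, `"numeric_above"` or `"label_in"`.
#' @param threshold numeric cut-off (numeric kinds only).
#' @param damaging_labels character vector of damaging labels
#'   (`"label_in"` only).
#' @param weight positive contribution to the cumulative score (default 1).
#' @return A `criterion` object.
#' @seealso [criteria_set()], [default_criteria()]
#' @export
criterion <- function(tool, kind, threshold = NULL, damaging_labels = NULL,
                      weight = 1) {
  kind <- match.arg(kind, c("numeric_below", "numeric_above", "label_in"))
  if (kind == "label_in") {
    if (is.null(damaging_labels) || !is.null(threshold)) {
      stop("criterion '", tool, "': label_in requires damaging_labels and no threshold")
    }
  } else {
    if (is.null(threshold) || !is.null(damaging_labels) ||
        !is.finite(threshold)) {
      stop("criterion '", tool, "': ", kind,
           " requires a finite threshold and no damaging_labels")
    }
  }
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0) {
    stop("criterion '", tool, "': weight must be a positive number")
  }
  structure(list(tool = tool, kind = kind, threshold = threshold,
                 damaging_labels = damaging_labels, weight = weight),
            class = "criterion")
}

#' Assemble a criteria registry
#'
#' An ordered set of [criterion()]s with unique tool names; the maximum
#' attainable cumulative score is the sum of the weights (derived, never
#' hard-coded).
#'
#' @param ... `criterion` objects, or a single list of them.
#' @return A `criteria_set` object with attribute `max_score`.
#' @export
criteria_set <- function(...) {
  crits <- list(...)
  if (length(crits) == 1L && !inherits(crits[[1L]], "criterion")) {
    crits <- crits[[1L]]
  }
  if (!length(crits) || !all(vapply(crits, inherits, logical(1), "criterion"))) {
    stop("criteria_set needs at least one criterion")
  }
  tools <- vapply(crits, `[[`, character(1), "tool")
  if (anyDuplicated(tools)) {
    stop("duplicate tool(s) in criteria set: ",
         paste(unique(tools[duplicated(tools)]), collapse = ", "))
  }
  names(crits) <- tools
  structure(crits, class = "criteria_set",
            max_score = sum(vapply(crits, `[[`, numeric(1), "weight")))
}

#' @export
print.criteria_set <- function(x, ...) {
  cat("criteria_set:", length(x), "criteria, max score",
      attr(x, "max_score"), "\n")
  for (cr in x) {
    rule <- switch(cr$kind,
      numeric_below = paste("<", cr$threshold),
      numeric_above = paste(">", cr$threshold),
      label_in = paste("in {", paste(cr$damaging_labels, collapse = ", "), "}")
    )
    cat(sprintf("  %-16s %-13s %-12s weight %g\n",
                cr$tool, cr$kind, rule, cr$weight))
  }
  invisible(x)
}

#' Default 14-criterion damaging registry
#'
#' The consensus registry used throughout: seven numeric rules
#' (SIFT < 0.05; PolyPhen2 > 0.8; CADD phred > 20; CADD raw > 2;
#' GERP++RS > 4; M-CAP > 0.025; LoFtool < 0.5) and seven categorical tools
#' (Condel, DANN, FATHMM, LRT, MetaLR, MutationTaster, PROVEAN) with
#' conventional dbNSFP-style damaging labels. CADD phred and raw are kept as
#' two criteria, so the registry has 14 unit-weight entries and a derived
#' maximum score of 14. Every rule, label vocabulary and weight is
#' remappable: build your own [criteria_set()] or load one with
#' [read_criteria()].
#'
#' @return A [criteria_set()] of 14 unit-weight criteria.
#' @export
default_criteria <- function() {
  criteria_set(
    criterion("SIFT",           "numeric_below", 0.05),
    criterion("PolyPhen2",      "numeric_above", 0.8),
    criterion("CADD_phred",     "numeric_above", 20),
    criterion("CADD_raw",       "numeric_above", 2),
    criterion("GERP++RS",       "numeric_above", 4),
    criterion("M-CAP",          "numeric_above", 0.025),
    criterion("LoFtool",        "numeric_below", 0.5),
    criterion("Condel",         "label_in", damaging_labels = "deleterious"),
    criterion("DANN",           "label_in", damaging_labels = "D"),
    criterion("FATHMM",         "label_in", damaging_labels = "D"),
    criterion("LRT",            "label_in", damaging_labels = "D"),
    criterion("MetaLR",         "label_in", damaging_labels = "D"),
    criterion("MutationTaster", "label_in", damaging_labels = c("A", "D")),
    criterion("PROVEAN",        "label_in", damaging_labels = "D")
  )
}

#' Load a criteria registry from a JSON or YAML config file
#'
#' The file holds a list of objects with fields `tool`, `kind`,
#' `threshold` or `damaging_labels`, and optional `weight`.
#'
#' @param file path to a `.json`, `.yaml` or `.yml` file.
#' @return A [criteria_set()].
#' @examples
#' reg <- read_criteria(system.file("extdata", "criteria20_synthetic.json",
#'                                  package = "pedprio"))
#' attr(reg, "max_score")
#' @export
read_criteria <- function(file) {
  raw <- if (grepl("\\.ya?ml$", file)) {
    yaml::read_yaml(file)
  } else {
    jsonlite::fromJSON(file, simplifyDataFrame = FALSE)
  }
  criteria_set(lapply(raw, function(x) {
    criterion(x$tool, x$kind,
              threshold = x$threshold,
              damaging_labels = if (!is.null(x$damaging_labels))
                unlist(x$damaging_labels),
              weight = if (is.null(x$weight)) 1 else x$weight)
  }))
}

#' Evaluate one criterion against one annotation profile
#'
#' @param profile named list (or one-row data frame) of tool values; absent
#'   or `NA` entries are missing.
#' @param crit a [criterion()].
#' @return `"satisfied"`, `"unsatisfied"` or `"missing"`.
#' @examples
#' evaluate_criterion(list(SIFT = 0.049), criterion("SIFT", "numeric_below", 0.05))
#' evaluate_criterion(list(SIFT = 0.05),  criterion("SIFT", "numeric_below", 0.05))
#' @export
evaluate_criterion <- function(profile, crit) {
  if (is.data.frame(profile)) profile <- as.list(profile)
  val <- profile[[crit$tool]]
  if (is.null(val) || length(val) == 0L || is.na(val)) return("missing")
  if (crit$kind == "label_in") {
    if (is.numeric(val)) {
      stop("criterion '", crit$tool,
           "' expects a categorical label but the value is numeric")
    }
    return(if (as.character(val) %in% crit$damaging_labels) "satisfied"
           else "unsatisfied")
  }
  if (!is.numeric(val)) {
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) {
      stop("criterion '", crit$tool,
           "' expects a numeric value but got label '", val, "'")
    }
    val <- num
  }
  hit <- switch(crit$kind,
    numeric_below = val < crit$threshold,
    numeric_above = val > crit$threshold
  )
  if (hit) "satisfied" else "unsatisfied"
}

#' Cumulative damaging score of one annotation profile
#'
#' The score is the sum of the weights of the satisfied criteria; missing
#' annotations contribute nothing and are flagged in the breakdown, so
#' sparsely annotated variants are neither advantaged nor silently penalized.
#' Higher scores indicate greater consensus for pathogenicity; the maximum
#' is the registry's summed weight.
#'
#' @inheritParams evaluate_criterion
#' @param cs a [criteria_set()].
#' @return List with `score`, `max_score`, `breakdown` (named character
#'   vector of per-tool verdicts) and `n_tools_deleterious` (satisfied
#'   criteria, weights ignored).
#' @export
damaging_score <- function(profile, cs) {
  stopifnot(inherits(cs, "criteria_set"))
  breakdown <- vapply(cs, function(cr) evaluate_criterion(profile, cr),
                      character(1))
  w <- vapply(cs, `[[`, numeric(1), "weight")
  list(score = sum(w[breakdown == "satisfied"]),
       max_score = attr(cs, "max_score"),
       breakdown = breakdown,
       n_tools_deleterious = sum(breakdown == "satisfied"))
}

#' Count tools calling a variant deleterious
#'
#' @inheritParams damaging_score
#' @return Integer: criteria with verdict satisfied, ignoring weights.
#' @export
count_deleterious_tools <- function(profile, cs) {
  damaging_score(profile, cs)$n_tools_deleterious
}

#' Score a whole annotation data frame against a registry
#'
#' Row-wise [damaging_score()], returned as columns: `score`,
#' `n_tools_deleterious` and one `tool_<name>` verdict column per criterion.
#'
#' @param ann data frame with one row per variant and tool columns.
#' @param cs a [criteria_set()].
#' @return `ann` with the score columns appended.
#' @export
score_variants <- function(ann, cs) {
  n <- nrow(ann)
  verdict <- matrix("missing", nrow = n, ncol = length(cs),
                    dimnames = list(NULL, names(cs)))
  for (cr in cs) {
    col <- ann[[cr$tool]]
    if (is.null(col)) next
    present <- !is.na(col)
    if (!any(present)) next
    if (cr$kind == "label_in") {
      if (is.numeric(col)) {
        stop("criterion '", cr$tool,
             "' expects a categorical label but the column is numeric")
      }
      hit <- as.character(col) %in% cr$damaging_labels
    } else {
      if (!is.numeric(col)) {
        stop("criterion '", cr$tool,
             "' expects a numeric value but the column is categorical")
      }
      hit <- if (cr$kind == "numeric_below") col < cr$threshold
             else col > cr$threshold
    }
    verdict[present & hit, cr$tool] <- "satisfied"
    verdict[present & !hit, cr$tool] <- "unsatisfied"
  }
  w <- vapply(cs, `[[`, numeric(1), "weight")
  ann$score <- as.vector((verdict == "satisfied") %*% w)
  ann$n_tools_deleterious <- rowSums(verdict == "satisfied")
  vcols <- as.data.frame(verdict, stringsAsFactors = FALSE)
  names(vcols) <- paste0("tool_", names(cs))
  cbind(ann, vcols)
}

#' Rank scored variants
#'
#' Orders by descending cumulative score; ties broken by descending CADD
#' phred, then ascending (chrom, pos). Ranks are 1-based and dense: rows
#' identical on the full sort key share a rank.
#'
#' @param scored data frame from [score_variants()] (needs `score`, `chrom`,
#'   `pos`; uses `CADD_phred` when present).
#' @return `scored`, sorted, with a `rank` column.
#' @export
rank_variants <- function(scored) {
  if (nrow(scored) == 0L) {
    scored$rank <- integer(0)
    return(scored)
  }
  cadd <- if ("CADD_phred" %in% names(scored)) scored$CADD_phred else
    rep(NA_real_, nrow(scored))
  cadd_key <- ifelse(is.na(cadd), -Inf, cadd)
  ord <- order(-scored$score, -cadd_key, scored$chrom, scored$pos)
  scored <- scored[ord, , drop = FALSE]
  cadd_key <- cadd_key[ord]
  new_rank <- c(TRUE, scored$score[-1L] != scored$score[-nrow(scored)] |
                      cadd_key[-1L] != cadd_key[-nrow(scored)] |
                      scored$chrom[-1L] != scored$chrom[-nrow(scored)] |
                      scored$pos[-1L] != scored$pos[-nrow(scored)])
  scored$rank <- cumsum(new_rank)
  rownames(scored) <- NULL
  scored
}
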