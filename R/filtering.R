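#' Filter configuration for the candidate cascade
#'
#' Holds every cut-off of the candidate-selection cascade: population
#' rarity, protein-impact consequence, dominant co-segregation, and the
#' known-gene pre-screen. The defaults are documented reconstructions of a
#' conventional dominant rare-variant workflow, not measured values: a MAF
#' threshold of 0.1% across all population databases and the
#' protein-altering consequence classes.
#'
#' @param maf_threshold population allele-frequency cut-off in `[0, 1]`;
#'   a variant fails when any present database frequency is `>=` this value
#'   (default 0.001).
#' @param required_consequences consequence whitelist (default missense,
#'   stop_gain, frameshift, splice, inframe_indel).
#' @param known_genes established disease genes to pre-screen and report
#'   (default APP, PSEN1, PSEN2 — the early-onset Alzheimer genes excluded
#'   by Sanger sequencing before genome-wide search).
#' @param af_columns annotation columns holding population frequencies
#'   (default `ExAC_AF`, `gnomAD_AF`, `KG1000_AF`).
#' @param model inheritance model for segregation (`"dominant"`).
#' @param min_informative minimum informative members for a segregation call.
#' @param missing_af_policy `"pass_flagged"` (default: a variant absent from
#'   every frequency database is consistent with being rare, so it passes but
#'   is flagged) or `"fail"`.
#' @return A `filter_config` object (list).
#' @export
filter_config <- function(maf_threshold = 0.001,
                          required_consequences = c("missense", "stop_gain",
                                                    "frameshift", "splice",
                                                    "inframe_indel"),
                          known_genes = c("APP", "PSEN1", "PSEN2"),
                          af_columns = c("ExAC_AF", "gnomAD_AF", "KG1000_AF"),
                          model = "dominant",
                          min_informative = 2L,
                          missing_af_policy = c("pass_flagged", "fail")) {
  missing_af_policy <- match.arg(missing_af_policy)
  stopifnot(is.numeric(maf_threshold), maf_threshold >= 0, maf_threshold <= 1)
  if (!length(known_genes)) stop("known_genes must be non-empty")
  structure(list(maf_threshold = maf_threshold,
                 required_consequences = required_consequences,
                 known_genes = known_genes,
                 af_columns = af_columns,
                 model = model,
                 min_informative = as.integer(min_informative),
                 missing_af_policy = missing_af_policy),
            class = "filter_config")
}

#' Load a filter configuration from JSON or YAML
#'
#' Keys mirror the [filter_config()] arguments; absent keys keep defaults.
#'
#' @param file path to a `.json`, `.yaml` or `.yml` file.
#' @return A `filter_config`.
#' @export
read_filter_config <- function(file) {
  raw <- if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
         else jsonlite::fromJSON(file, simplifyDataFrame = FALSE)
  raw <- raw[names(raw) %in% names(formals(filter_config))]
  do.call(filter_config, raw)
}

#' Population-rarity filter
#'
#' A variant fails when any present database frequency reaches the
#' threshold. A variant observed in no database passes flagged (or fails,
#' per `missing_af_policy`): a never-observed allele is consistent with
#' being rare.
#'
#' @param afs named numeric vector of population allele frequencies (may be
#'   empty or hold `NA`s), or a data frame/list with the configured
#'   frequency columns.
#' @param cfg a [filter_config()].
#' @return `"pass"`, `"pass_flagged"` or `"fail"` (vectorized over data
#'   frame rows).
#' @examples
#' maf_filter(c(ExAC_AF = 3.295e-05, gnomAD_AF = 1.589e-05,
#'              KG1000_AF = 1.997e-04), filter_config())
#' @export
maf_filter <- function(afs, cfg = filter_config()) {
  if (is.data.frame(afs)) {
    cols <- intersect(cfg$af_columns, names(afs))
    m <- if (length(cols)) as.matrix(afs[, cols, drop = FALSE])
         else matrix(NA_real_, nrow = nrow(afs), ncol = 0L)
    any_fail <- if (ncol(m)) rowSums(m >= cfg$maf_threshold, na.rm = TRUE) > 0
                else rep(FALSE, nrow(afs))
    none_present <- if (ncol(m)) rowSums(!is.na(m)) == 0L
                    else rep(TRUE, nrow(afs))
    out <- rep("pass", nrow(afs))
    out[none_present] <- if (cfg$missing_af_policy == "pass_flagged")
      "pass_flagged" else "fail"
    out[any_fail] <- "fail"
    return(out)
  }
  afs <- afs[!is.na(afs)]
  if (!length(afs)) {
    return(if (cfg$missing_af_policy == "pass_flagged") "pass_flagged" else "fail")
  }
  if (any(afs >= cfg$maf_threshold)) "fail" else "pass"
}

#' Protein-impact consequence filter
#'
#' Whitelist membership: `TRUE` iff the consequence is one of the configured
#' protein-altering classes. Missing consequences fail (they cannot be shown
#' to alter the protein).
#'
#' @param consequence character vector of consequence terms.
#' @param cfg a [filter_config()].
#' @return Logical vector.
#' @export
consequence_filter <- function(consequence, cfg = filter_config()) {
  !is.na(consequence) & consequence %in% cfg$required_consequences
}

#' Dominant co-segregation filter for one variant
#'
#' Delegates to [cosegregation_check()]; the variant passes iff it
#' segregates.
#'
#' @param genotypes named alternate-allele counts for one variant.
#' @param ped a [pedigree()].
#' @param cfg a [filter_config()].
#' @return A `segregation_result`.
#' @export
segregation_filter <- function(genotypes, ped, cfg = filter_config()) {
  cosegregation_check(ped, genotypes, model = cfg$model,
                      min_informative = cfg$min_informative)
}

#' Known-gene pre-screen
#'
#' Reports (without excluding) the records whose gene is an established
#' disease gene from the configuration — the analogue of checking the known
#' genes before any genome-wide search, so a hit there is surfaced rather
#' than buried in the ranking.
#'
#' @param ann data frame with a `gene` column.
#' @param cfg a [filter_config()].
#' @return The sub-data-frame of records in known genes (possibly 0-row).
#' @export
known_gene_screen <- function(ann, cfg = filter_config()) {
  if (!"gene" %in% names(ann)) return(ann[integer(0), , drop = FALSE])
  ann[!is.na(ann$gene) & ann$gene %in% cfg$known_genes, , drop = FALSE]
}

#' Apply the candidate-selection cascade
#'
#' Stages, in order: protein-impact consequence, population rarity,
#' dominant co-segregation. Survivor order is preserved and a funnel log
#' records `(stage, n_in, n_pass, n_fail)` per stage, with
#' `n_in = n_pass + n_fail` and each stage fed by the previous stage's
#' passes.
#'
#' @param ann data frame with one row per variant: key columns plus
#'   `consequence` and frequency columns.
#' @param geno integer matrix of alternate-allele counts (rows match `ann`
#'   rows, columns are sample ids).
#' @param ped a [pedigree()].
#' @param cfg a [filter_config()].
#' @return List with `survivors` (row-subset of `ann` plus `maf_flagged` and
#'   segregation columns), `survivor_idx` (row indices into `ann`), and
#'   `funnel` (data frame).
#' @export
apply_cascade <- function(ann, geno, ped, cfg = filter_config()) {
  stopifnot(nrow(ann) == nrow(geno))
  funnel <- data.frame(stage = character(), n_in = integer(),
                       n_pass = integer(), n_fail = integer(),
                       stringsAsFactors = FALSE)
  add_stage <- function(funnel, stage, keep_in) {
    rbind(funnel, data.frame(stage = stage, n_in = length(keep_in),
                             n_pass = sum(keep_in), n_fail = sum(!keep_in),
                             stringsAsFactors = FALSE))
  }
  idx <- seq_len(nrow(ann))

  cons_ok <- consequence_filter(
    if ("consequence" %in% names(ann)) ann$consequence[idx]
    else rep(NA_character_, length(idx)), cfg)
  funnel <- add_stage(funnel, "consequence", cons_ok)
  idx <- idx[cons_ok]

  maf_v <- maf_filter(ann[idx, , drop = FALSE], cfg)
  maf_ok <- maf_v != "fail"
  funnel <- add_stage(funnel, "rarity", maf_ok)
  idx <- idx[maf_ok]
  maf_flagged <- maf_v[maf_ok] == "pass_flagged"

  seg <- lapply(idx, function(i) {
    g <- geno[i, ]
    names(g) <- colnames(geno)
    segregation_filter(g, ped, cfg)
  })
  seg_ok <- vapply(seg, `[[`, logical(1), "segregates")
  funnel <- add_stage(funnel, "segregation", seg_ok)

  surv_idx <- idx[seg_ok]
  survivors <- ann[surv_idx, , drop = FALSE]
  if (nrow(survivors)) {
    survivors$maf_flagged <- maf_flagged[seg_ok]
    keep <- seg[seg_ok]
    survivors$n_informative <- vapply(keep, `[[`, integer(1), "n_informative")
    survivors$n_consistent <- vapply(keep, `[[`, integer(1), "n_consistent")
    survivors$n_violations <- vapply(keep, `[[`, integer(1), "n_violations")
    survivors$segregates <- TRUE
  } else {
    survivors$maf_flagged <- logical(0)
    survivors$n_informative <- integer(0)
    survivors$n_consistent <- integer(0)
    survivors$n_violations <- integer(0)
    survivors$segregates <- logical(0)
  }
  rownames(survivors) <- NULL
  list(survivors = survivors, survivor_idx = surv_idx, funnel = funnel)
}
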