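#' Four-generation, 23-member pedigree template
#'
#' A synthetic reconstruction of a multigenerational family segregating a
#' fully penetrant dominant trait: 23 members across four generations, 8
#' affected (including the deceased founder through whom the allele enters),
#' 11 unaffected and 4 of unknown status. The seven members conventionally
#' genotyped (II-1 and III-2..III-5 affected; II-2, an aunt, and III-8, a
#' cousin, unaffected) sit in their stated relationships. The exact topology
#' beyond those constraints is the package's own construction.
#'
#' @return A [pedigree()] of 23 members.
#' @export
ped_template_ad23 <- function() {
  read_ped(system.file("extdata", "family23_synthetic.ped",
                       package = "pedprio"))
}

#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates: a rare, fully
#' penetrant autosomal-dominant causal variant entering through one founder
#' of a multigenerational family, against a background of unlinked rare
#' variants at population frequencies, with per-tool predictor profiles that
#' sit on the damaging side (causal) or benign side (background) of each
#' criterion apart from a small per-tool noise rate.
#'
#' @param pedigree_template `"ad23"` (the 23-member four-generation family,
#'   [ped_template_ad23()]) or a [pedigree()] of your own.
#' @param n_background_variants background variants (default 500).
#' @param background_af_alpha,background_af_beta Beta distribution shape
#'   parameters for background founder allele frequencies (defaults 0.5 and
#'   50: a rare-variant site-frequency profile, median AF ~0.5%).
#' @param causal_founder_id founder carrying the planted variant
#'   (default `"I-1"`); `NA` to plant no causal variant.
#' @param penetrance P(affected | carrier), default 1 (fully penetrant).
#' @param phenocopy_rate P(affected | non-carrier), default 0.
#' @param annotation_noise per-criterion probability a simulated value falls
#'   on the wrong side of its rule (default 0.1).
#' @param sequenced_subset ids genotyped in the emitted VCF (default the
#'   seven members II-1, III-2..III-5, II-2, III-8).
#' @param fixed_phenotypes if `TRUE`, keep the template's recorded affection
#'   statuses instead of simulating them from carrier state.
#' @param criteria registry the annotation profiles are simulated against.
#' @param seed integer seed; every draw is reproducible under it.
#' @return A `simulation_config` (list).
#' @export
simulation_config <- function(pedigree_template = "ad23",
                              n_background_variants = 500L,
                              background_af_alpha = 0.5,
                              background_af_beta = 50,
                              causal_founder_id = "I-1",
                              penetrance = 1,
                              phenocopy_rate = 0,
                              annotation_noise = 0.1,
                              sequenced_subset = c("II-1", "III-2", "III-3",
                                                   "III-4", "III-5", "II-2",
                                                   "III-8"),
                              fixed_phenotypes = FALSE,
                              criteria = default_criteria(),
                              seed = 1L) {
  ped <- if (inherits(pedigree_template, "pedigree")) pedigree_template
         else switch(pedigree_template,
                     ad23 = ped_template_ad23(),
                     stop("unknown pedigree template: ", pedigree_template))
  stopifnot(penetrance >= 0, penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1,
            annotation_noise >= 0, annotation_noise <= 1,
            n_background_variants >= 0)
  if (!is.na(causal_founder_id)) {
    founders <- ped$individual_id[is.na(ped$father_id) & is.na(ped$mother_id)]
    if (!causal_founder_id %in% founders) {
      stop("causal_founder_id '", causal_founder_id,
           "' is not a founder of the template")
    }
  }
  stopifnot(all(sequenced_subset %in% ped$individual_id))
  structure(list(pedigree = ped,
                 n_background_variants = as.integer(n_background_variants),
                 background_af_alpha = background_af_alpha,
                 background_af_beta = background_af_beta,
                 causal_founder_id = causal_founder_id,
                 penetrance = penetrance,
                 phenocopy_rate = phenocopy_rate,
                 annotation_noise = annotation_noise,
                 sequenced_subset = sequenced_subset,
                 fixed_phenotypes = fixed_phenotypes,
                 criteria = criteria,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Drop genotypes down a pedigree by Mendelian transmission
#'
#' Each non-founder receives one allele drawn uniformly from each parent's
#' two alleles. Founders keep the genotypes supplied; every founder must
#' have one.
#'
#' @param ped a [pedigree()].
#' @param founder_genotypes named alternate-allele counts (0/1/2) for every
#'   founder.
#' @param seed optional integer; when given, draws are reproducible.
#' @return Named integer vector of allele counts for all members.
#' @examples
#' trio <- pedigree(c("F", "M", "C"), c(NA, NA, "F"), c(NA, NA, "M"))
#' gene_drop(trio, c(F = 1, M = 0), seed = 42)
#' @export
gene_drop <- function(ped, founder_genotypes, seed = NULL) {
  drop_fun <- function() {
    ids <- ped$individual_id
    founders <- ids[is.na(ped$father_id) & is.na(ped$mother_id)]
    missing_f <- setdiff(founders, names(founder_genotypes))
    if (length(missing_f)) {
      stop("missing founder genotype(s): ", paste(missing_f, collapse = ", "))
    }
    g <- setNames(rep(NA_integer_, length(ids)), ids)
    g[founders] <- as.integer(founder_genotypes[founders])
    repeat {
      todo <- ids[is.na(g)]
      if (!length(todo)) break
      for (id in todo) {
        i <- match(id, ids)
        # a parent outside the pedigree is assumed non-carrier
        fa <- if (is.na(ped$father_id[i])) 0L else g[[ped$father_id[i]]]
        mo <- if (is.na(ped$mother_id[i])) 0L else g[[ped$mother_id[i]]]
        if (is.na(fa) || is.na(mo)) next
        g[id] <- stats::rbinom(1L, 1L, fa / 2) + stats::rbinom(1L, 1L, mo / 2)
      }
    }
    g
  }
  if (is.null(seed)) drop_fun() else with_seed(seed, drop_fun())
}

#' Assign affection status from carrier state
#'
#' A carrier is affected with probability `penetrance`; a non-carrier with
#' probability `phenocopy_rate`. Individuals with missing genotype get
#' unknown affection.
#'
#' @param genotypes named alternate-allele counts.
#' @param penetrance,phenocopy_rate probabilities in `[0, 1]`.
#' @param seed optional integer for reproducibility.
#' @return Named character vector (`"affected"` / `"unaffected"` /
#'   `"unknown"`).
#' @export
assign_phenotypes <- function(genotypes, penetrance = 1, phenocopy_rate = 0,
                              seed = NULL) {
  fun <- function() {
    carrier <- !is.na(genotypes) & genotypes >= 1L
    p <- ifelse(carrier, penetrance, phenocopy_rate)
    aff <- ifelse(stats::runif(length(genotypes)) < p, "affected", "unaffected")
    aff[is.na(genotypes)] <- "unknown"
    setNames(aff, names(genotypes))
  }
  if (is.null(seed)) fun() else with_seed(seed, fun())
}

#' Simulate per-tool annotation profiles
#'
#' For each criterion of the registry, draws a value on the damaging side
#' (`"causal_damaging"` class) or benign side (`"benign"`) of its rule,
#' flipped to the other side with probability `noise`. Numeric draws are
#' uniform within the side's range on the tool's documented scale; label
#' draws use the registry's damaging labels versus a benign label.
#'
#' @param variant_class `"causal_damaging"` or `"benign"` (vectorized:
#'   one profile per element).
#' @param cs a [criteria_set()].
#' @param noise per-criterion flip probability in `[0, 1]`.
#' @param seed optional integer for reproducibility.
#' @param ranges optional per-tool list of `damaging = c(lo, hi)` /
#'   `benign = c(lo, hi)` numeric draw ranges overriding
#'   [default_tool_ranges()].
#' @return Data frame with one row per requested profile and one column per
#'   tool.
#' @export
simulate_annotation_profiles <- function(variant_class, cs = default_criteria(),
                                         noise = 0.1, seed = NULL,
                                         ranges = NULL) {
  fun <- function() {
    n <- length(variant_class)
    stopifnot(all(variant_class %in% c("causal_damaging", "benign")))
    rng <- default_tool_ranges(cs)
    if (!is.null(ranges)) rng[names(ranges)] <- ranges
    out <- vector("list", length(cs))
    names(out) <- names(cs)
    damaging_target <- variant_class == "causal_damaging"
    for (cr in cs) {
      flip <- stats::runif(n) < noise
      damaging <- xor(damaging_target, flip)
      if (cr$kind == "label_in") {
        benign_label <- rng[[cr$tool]]$benign_label
        vals <- ifelse(damaging,
                       cr$damaging_labels[1L],
                       benign_label)
      } else {
        r <- rng[[cr$tool]]
        lo <- ifelse(damaging, r$damaging[1L], r$benign[1L])
        hi <- ifelse(damaging, r$damaging[2L], r$benign[2L])
        vals <- stats::runif(n, lo, hi)
      }
      out[[cr$tool]] <- vals
    }
    as.data.frame(out, optional = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  }
  if (is.null(seed)) fun() else with_seed(seed, fun())
}

#' Default numeric draw ranges per tool
#'
#' Uniform draw windows on each tool's documented scale, split at the
#' registry threshold: e.g. benign SIFT ~ U(0.05, 1), damaging
#' SIFT ~ U(0, 0.05). For label criteria, supplies the benign label drawn
#' against the registry's damaging vocabulary.
#'
#' @param cs a [criteria_set()].
#' @return Named list, one entry per criterion.
#' @export
default_tool_ranges <- function(cs = default_criteria()) {
  scale_hint <- list(
    SIFT = c(0, 1), PolyPhen2 = c(0, 1), CADD_phred = c(0, 40),
    CADD_raw = c(-3, 8), `GERP++RS` = c(-12.3, 6.17), `M-CAP` = c(0, 1),
    LoFtool = c(0, 1)
  )
  benign_hint <- c(Condel = "neutral", DANN = "T", FATHMM = "T", LRT = "N",
                   MetaLR = "T", MutationTaster = "N", PROVEAN = "N")
  out <- list()
  for (cr in cs) {
    if (cr$kind == "label_in") {
      bl <- if (cr$tool %in% names(benign_hint)) benign_hint[[cr$tool]] else "benign"
      if (bl %in% cr$damaging_labels) bl <- "benign"
      out[[cr$tool]] <- list(benign_label = bl)
    } else {
      sc <- if (cr$tool %in% names(scale_hint)) scale_hint[[cr$tool]]
            else c(cr$threshold - 10, cr$threshold + 10)
      if (cr$kind == "numeric_below") {
        out[[cr$tool]] <- list(damaging = c(sc[1L], cr$threshold),
                               benign = c(cr$threshold, sc[2L]))
      } else {
        out[[cr$tool]] <- list(damaging = c(cr$threshold, sc[2L]),
                               benign = c(sc[1L], cr$threshold))
      }
    }
  }
  out
}

#' Generate a complete synthetic family dataset
#'
#' Plants one fully penetrant dominant causal variant in the configured
#' founder, gene-drops it and `n_background_variants` unlinked background
#' variants (founder genotypes drawn by Hardy-Weinberg at Beta-distributed
#' allele frequencies) down the pedigree, assigns phenotypes from carrier
#' state under the penetrance/phenocopy model (unless `fixed_phenotypes`),
#' simulates damaging-side annotation profiles for the causal variant and
#' benign-side profiles for the background, and restricts genotypes to the
#' sequenced subset. Fully reproducible under the config seed.
#'
#' @param config a [simulation_config()].
#' @param dir optional directory; when given, writes `sim.vcf`, `sim.ped`,
#'   `sim_annotations.tsv` and `sim_truth.json` there.
#' @return List with `vset` (a `variant_set` over the sequenced subset),
#'   `ped` (the template pedigree with simulated affection), `annotations`
#'   (an `annotation_table`), `truth` (list with `causal_key`,
#'   `causal_founder_id`, `carriers`), and `files` (paths, when `dir` was
#'   given).
#' @examples
#' sim <- simulate_family_dataset(simulation_config(seed = 7))
#' sim$truth$causal_key
#' @export
simulate_family_dataset <- function(config = simulation_config(), dir = NULL) {
  with_seed(config$seed, {
    ped <- config$pedigree
    ids <- ped$individual_id
    founders <- ids[is.na(ped$father_id) & is.na(ped$mother_id)]
    plant <- !is.na(config$causal_founder_id)
    n_bg <- config$n_background_variants
    n_var <- n_bg + as.integer(plant)

    # founder allele frequencies: causal variant is absent from the
    # population (enters through one founder only)
    af <- stats::rbeta(n_bg, config$background_af_alpha,
                       config$background_af_beta)

    geno_all <- matrix(NA_integer_, nrow = n_var, ncol = length(ids),
                       dimnames = list(NULL, ids))
    causal_row <- if (plant) 1L else 0L
    if (plant) {
      fg <- setNames(rep(0L, length(founders)), founders)
      fg[config$causal_founder_id] <- 1L
      geno_all[1L, ] <- gene_drop(ped, fg)
    }
    for (b in seq_len(n_bg)) {
      fg <- setNames(stats::rbinom(length(founders), 2L, af[b]), founders)
      geno_all[causal_row + b, ] <- gene_drop(ped, fg)
    }

    if (!config$fixed_phenotypes && plant) {
      aff <- assign_phenotypes(setNames(geno_all[1L, ], ids),
                               config$penetrance, config$phenocopy_rate)
      ped$affection <- unname(aff[ids])
    }

    # variant coordinates: synthetic chromosome-per-block layout
    chrom <- as.character(1 + ((seq_len(n_var) - 1L) %% 22L))
    pos <- 10000L + 100L * seq_len(n_var)
    ref <- rep(c("A", "C", "G", "T"), length.out = n_var)
    alt <- rep(c("G", "T", "A", "C"), length.out = n_var)
    variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                           stringsAsFactors = FALSE)
    vset <- new_variant_set(variants,
                            geno_all[, config$sequenced_subset, drop = FALSE])

    cls <- rep("benign", n_var)
    if (plant) cls[1L] <- "causal_damaging"
    prof <- simulate_annotation_profiles(cls, config$criteria,
                                         noise = config$annotation_noise)
    ann <- cbind(variants,
                 gene = sprintf("GENE%04d", seq_len(n_var)),
                 consequence = "missense",
                 ExAC_AF = c(if (plant) NA_real_ else NULL, af),
                 prof, stringsAsFactors = FALSE)
    ann$key <- variant_key(ann)
    ann <- ann[, c("key", setdiff(names(ann), "key"))]
    class(ann) <- c("annotation_table", "data.frame")

    truth <- list(
      causal_key = if (plant) vset$variants$key[1L] else NA_character_,
      causal_founder_id = config$causal_founder_id,
      carriers = if (plant) names(which(geno_all[1L, ] >= 1L)) else character(0)
    )

    files <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files <- list(vcf = file.path(dir, "sim.vcf"),
                    ped = file.path(dir, "sim.ped"),
                    annotations = file.path(dir, "sim_annotations.tsv"),
                    truth = file.path(dir, "sim_truth.json"))
      write_vcf(vset, files$vcf)
      write_ped(ped, files$ped)
      tsv <- ann[, setdiff(names(ann), "key")]
      tsv[] <- lapply(tsv, function(x) ifelse(is.na(x), ".", as.character(x)))
      utils::write.table(tsv, files$annotations, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(truth, files$truth, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    list(vset = vset, ped = ped, annotations = ann, truth = truth,
         files = files)
  })
}
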