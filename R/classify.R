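#' Allele fate categories
#'
#' The taxonomy used throughout: `excluded` and `emerged` are the allele
#' "zero/one" changes; `restored` marks reappearance from an earlier source
#' population (e.g. wild accessions used as direct breeding parents);
#' the `inherited_*` categories split inherited alleles into kept fixation
#' (`inherited_fixed`), locus polymorphism disappeared / emerged / restored
#' (`inherited_LPD`, `inherited_LPE`, `inherited_LPR`) and ordinary frequency
#' changes; `absent_both` alleles stay at frequency 0; `unclassifiable`
#' flags alleles whose locus has an undefined frequency (all calls missing)
#' in a population needed for the comparison.
#'
#' @return character vector of category levels, in reporting order
#' @export
alleleFateLevels <- function() {
    c("excluded", "emerged", "restored",
      "inherited_fixed", "inherited_LPD", "inherited_LPE", "inherited_LPR",
      "inherited_increase", "inherited_decrease", "inherited_unchanged",
      "absent_both", "unclassifiable")
}

#' Locus fate categories
#' @return character vector of locus-level category levels
#' @export
locusFateLevels <- function() {
    c("polymorphism_disappeared", "polymorphism_emerged",
      "polymorphism_restored", "fixed_kept", "fixed_replaced",
      "polymorphic_kept", "absent")
}

#' Specify one ancestor-to-descendant transition
#'
#' @param parent,child subpopulation labels of the ancestral and derived
#'   stages
#' @param years duration of the transition in years (e.g. 5000 for
#'   domestication, 100 for modern breeding), used for per-year rates
#' @param sources ordered character vector of earlier stage labels that can
#'   act as restoration sources (empty for a first transition)
#' @param label transition label, default `"parent->child"`
#' @return a `transitionSpec` list
#' @export
transitionSpec <- function(parent, child, years, sources = character(),
                           label = paste0(parent, "->", child)) {
    stopifnot(is.character(parent), is.character(child),
              parent != child, years > 0)
    structure(list(parent = parent, child = child, years = as.numeric(years),
                   sources = as.character(sources), label = label),
              class = "transitionSpec")
}

#' Read an ordered stage graph from a YAML config
#'
#' Expected layout:
#' ```yaml
#' transitions:
#'   - parent: WA
#'     child: LR
#'     years: 5000
#'   - parent: LR
#'     child: RC
#'     years: 100
#'     sources: [WA]
#' ```
#'
#' @param path YAML file path
#' @return list of [transitionSpec()] objects
#' @export
readStageGraph <- function(path) {
    if (!file.exists(path))
        stop("stage-graph config not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$transitions) || !length(cfg$transitions))
        stop("config has no 'transitions' entries")
    lapply(cfg$transitions, function(tr) {
        if (is.null(tr$parent) || is.null(tr$child) || is.null(tr$years))
            stop("each transition needs 'parent', 'child' and 'years'")
        transitionSpec(tr$parent, tr$child, tr$years,
                       sources = unlist(tr$sources %||% character()))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify every universe allele at one transition
#'
#' Applies the frequency-predicate taxonomy to each allele of the shared
#' universe, with parent frequency `p`, child frequency `c` and frequencies
#' `s_i` in the configured restoration sources:
#' \itemize{
#'   \item `excluded`: p > 0, c = 0
#'   \item `emerged`: p = 0, c > 0, and 0 in every restoration source
#'   \item `restored`: p = 0, c > 0, > 0 in at least one source
#'   \item `absent_both`: p = 0, c = 0
#'   \item inherited (p > 0, c > 0): `inherited_fixed` (p = c = 1),
#'     `inherited_LPD` (p < 1, c = 1), `inherited_LPE` (p = 1, c < 1, and 1
#'     in all sources -- the first decrease from fixation),
#'     `inherited_LPR` (p = 1, c < 1, with some source < 1),
#'     `inherited_increase` (p < c < 1), `inherited_decrease` (c < p < 1),
#'     `inherited_unchanged` (0 < p = c < 1)
#' }
#' Alleles of a locus with undefined frequency (all calls missing) in the
#' parent, child or any source are `unclassifiable`; they are itemised and
#' excluded from percentage denominators downstream.
#'
#' @param freqs allele frequency table from [alleleFrequencies()] (or any
#'   data.frame with `locus_id`, `allele` and one frequency column per
#'   population)
#' @param spec a [transitionSpec()]
#' @return data.frame: `locus_id`, `allele`, `transition`, `category`
#'   (factor over [alleleFateLevels()]), `parent_freq`, `child_freq`
#' @export
classifyTransition <- function(freqs, spec) {
    stopifnot(inherits(spec, "transitionSpec"))
    need <- c(spec$parent, spec$child, spec$sources)
    miss <- setdiff(need, colnames(freqs))
    if (length(miss))
        stop("population(s) absent from the frequency table: ",
             paste(miss, collapse = ", "))
    p <- freqs[[spec$parent]]
    cc <- freqs[[spec$child]]
    smat <- if (length(spec$sources))
        as.matrix(freqs[, spec$sources, drop = FALSE]) else NULL

    undef <- is.na(p) | is.na(cc)
    if (!is.null(smat)) undef <- undef | rowSums(is.na(smat)) > 0L

    in_source <- if (is.null(smat)) rep(FALSE, nrow(freqs))
                 else rowSums(smat > 0, na.rm = TRUE) > 0L
    src_all_fixed <- if (is.null(smat)) rep(TRUE, nrow(freqs))
                     else rowSums(smat < 1, na.rm = TRUE) == 0L

    cat <- rep(NA_character_, nrow(freqs))
    cat[undef] <- "unclassifiable"
    ok <- !undef
    cat[ok & p > 0 & cc == 0] <- "excluded"
    cat[ok & p == 0 & cc == 0] <- "absent_both"
    cat[ok & p == 0 & cc > 0 & !in_source] <- "emerged"
    cat[ok & p == 0 & cc > 0 & in_source] <- "restored"
    inh <- ok & p > 0 & cc > 0
    cat[inh & p == 1 & cc == 1] <- "inherited_fixed"
    cat[inh & p < 1 & cc == 1] <- "inherited_LPD"
    cat[inh & p == 1 & cc < 1 & src_all_fixed] <- "inherited_LPE"
    cat[inh & p == 1 & cc < 1 & !src_all_fixed] <- "inherited_LPR"
    interior <- inh & p < 1 & cc < 1
    cat[interior & p < cc] <- "inherited_increase"
    cat[interior & p > cc] <- "inherited_decrease"
    cat[interior & p == cc] <- "inherited_unchanged"

    data.frame(locus_id = freqs$locus_id, allele = freqs$allele,
               transition = spec$label,
               category = factor(cat, levels = alleleFateLevels()),
               parent_freq = p, child_freq = cc,
               stringsAsFactors = FALSE)
}

#' Derive one locus-level fate per locus from its allele fates
#'
#' A locus is `polymorphism_disappeared` when one of its alleles is
#' `inherited_LPD` (frequency increased to 1), `polymorphism_emerged` when
#' one is `inherited_LPE` (first decrease from 1), `polymorphism_restored`
#' when one is `inherited_LPR`. A locus monomorphic in both populations is
#' `fixed_kept` (same allele) or `fixed_replaced` (a different allele fixed
#' in the child -- also used for the residual corners where the child fixes
#' or gains alleles the parent never carried). Loci polymorphic in both
#' populations are `polymorphic_kept`; loci with unclassifiable alleles are
#' `absent`.
#'
#' @param fates allele fate table from [classifyTransition()]
#' @return data.frame: `locus_id`, `transition`, `category` (factor over
#'   [locusFateLevels()])
#' @export
deriveLocusFates <- function(fates) {
    sp <- split(seq_len(nrow(fates)), fates$locus_id)
    lid <- names(sp)
    cat <- vapply(sp, function(rows) {
        cats <- as.character(fates$category[rows])
        p <- fates$parent_freq[rows]
        cc <- fates$child_freq[rows]
        if (any(cats == "unclassifiable")) return("absent")
        if (any(cats == "inherited_LPD")) return("polymorphism_disappeared")
        if (any(cats == "inherited_LPE")) return("polymorphism_emerged")
        if (any(cats == "inherited_LPR")) return("polymorphism_restored")
        p_fixed <- any(p == 1)
        c_fixed <- any(cc == 1)
        if (p_fixed && c_fixed) {
            if (any(p == 1 & cc == 1)) return("fixed_kept")
            return("fixed_replaced")
        }
        if (c_fixed) return("fixed_replaced")  # fixed on a non-inherited allele
        if (p_fixed) return("fixed_replaced")  # parent fixation broken without LPE/LPR
        "polymorphic_kept"
    }, character(1))
    data.frame(locus_id = lid,
               transition = fates$transition[vapply(sp, `[`, 0L, 1L)],
               category = factor(cat, levels = locusFateLevels()),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Chain allele fates along a path of transitions
#'
#' Classifies every transition of an ordered path (the child of each spec
#' must be the parent of the next) and joins the per-allele category
#' sequences, deriving successional flags:
#' \itemize{
#'   \item `permanently_excluded`: excluded at some transition and absent
#'     (frequency 0) at every later stage
#'   \item `emerged_then_inherited`: emerged at some transition and inherited
#'     at every later one
#'   \item `exclusion_after_decrease`: excluded at a transition whose
#'     predecessor showed an ordinary frequency decrease
#'   \item `fixation_after_increase`: frequency increased to 1 at a
#'     transition whose predecessor showed an ordinary frequency increase
#' }
#'
#' @param freqs allele frequency table (see [classifyTransition()])
#' @param specs list of [transitionSpec()] forming a path
#' @return data.frame with `locus_id`, `allele`, one category column per
#'   transition label, `final_freq` (frequency in the last stage) and the
#'   four logical flag columns
#' @export
chainFates <- function(freqs, specs) {
    if (!length(specs)) stop("empty transition list")
    for (i in seq_along(specs)[-1])
        if (specs[[i]]$parent != specs[[i - 1]]$child)
            stop("transitions do not form a path: '", specs[[i - 1]]$child,
                 "' is followed by parent '", specs[[i]]$parent, "'")
    fl <- lapply(specs, function(s) classifyTransition(freqs, s))
    labs <- vapply(specs, `[[`, character(1), "label")
    out <- data.frame(locus_id = freqs$locus_id, allele = freqs$allele,
                      stringsAsFactors = FALSE)
    cats <- matrix(NA_character_, nrow(freqs), length(specs))
    for (i in seq_along(fl)) {
        cats[, i] <- as.character(fl[[i]]$category)
        out[[labs[i]]] <- fl[[i]]$category
    }
    k <- length(specs)
    inh_set <- c("inherited_fixed", "inherited_LPD", "inherited_LPE",
                 "inherited_LPR", "inherited_increase", "inherited_decrease",
                 "inherited_unchanged")

    perm_excl <- rep(FALSE, nrow(freqs))
    emer_inh <- rep(FALSE, nrow(freqs))
    for (i in seq_len(k)) {
        later_absent <- if (i < k)
            rowSums(cats[, (i + 1):k, drop = FALSE] != "absent_both") == 0L
        else TRUE
        later_inh <- if (i < k)
            rowSums(!matrix(cats[, (i + 1):k, drop = FALSE] %in% inh_set,
                            nrow = nrow(cats))) == 0L
        else TRUE
        perm_excl <- perm_excl | (cats[, i] == "excluded" & later_absent)
        emer_inh <- emer_inh | (cats[, i] == "emerged" & later_inh)
    }
    excl_after_dec <- rep(FALSE, nrow(freqs))
    fix_after_inc <- rep(FALSE, nrow(freqs))
    if (k >= 2) for (i in 2:k) {
        excl_after_dec <- excl_after_dec |
            (cats[, i] == "excluded" & cats[, i - 1] == "inherited_decrease")
        fix_after_inc <- fix_after_inc |
            (cats[, i] == "inherited_LPD" &
             cats[, i - 1] == "inherited_increase")
    }
    out$final_freq <- freqs[[specs[[k]]$child]]
    out$permanently_excluded <- perm_excl
    out$emerged_then_inherited <- emer_inh
    out$exclusion_after_decrease <- excl_after_dec
    out$fixation_after_increase <- fix_after_inc
    out
}

#' Per-year change rates
#'
#' `perYear = count / years` and `perYearPerUnit = perYear / universe`, the
#' universe being the whole-population allele (or locus) total. Reported
#' values are rounded to 2 decimals and 3 significant figures respectively,
#' matching the conventional table format; raw values are returned alongside.
#'
#' @param count number of events (e.g. excluded alleles), non-negative
#' @param years transition duration in years, > 0
#' @param universe whole-population allele or locus total, > 0
#' @return data.frame with `count`, `years`, `universe`, `perYear`,
#'   `perYearPerUnit` (rounded as above) and `perYearRaw`, `perYearPerUnitRaw`
#' @examples
#' perYearRates(76866, 5000, 559611)  # 15.37 excluded alleles/year, 2.75e-05
#' @export
perYearRates <- function(count, years, universe) {
    if (any(count < 0)) stop("'count' must be non-negative")
    stopifnot(all(years > 0), all(universe > 0))
    per_year <- count / years
    per_unit <- per_year / universe
    data.frame(count = count, years = years, universe = universe,
               perYear = round(per_year, 2),
               perYearPerUnit = signif(per_unit, 3),
               perYearRaw = per_year, perYearPerUnitRaw = per_unit)
}

#' Group allele fates into evolutionary motivators
#'
#' Combines allele- and locus-level zero/one changes on the common scale of
#' allele counts ("allele + allele*"): Exclusion = excluded alleles +
#' inherited alleles that fixed their locus (LPD); Emergence = emerged
#' alleles + first decreases from fixation (LPE); Restoration = directly
#' restored alleles + restored decreases from fixation (LPR); Ordinary =
#' ordinary frequency increase + decrease; NoChange = alleles kept at
#' frequency 0 or 1. Ties (`inherited_unchanged`) are reported as their own
#' group rather than silently binned. Percentages are of the allele universe,
#' excluding unclassifiable alleles (which are itemised in the attribute
#' `"n_unclassifiable"`).
#'
#' @param fates allele fate table from [classifyTransition()]
#' @param universe allele universe size for percentages; default the number
#'   of classifiable fates
#' @return data.frame: `group`, `n_allele`, `n_allele_star`, `n_total`,
#'   `pct_allele`, `pct_allele_star`, `pct_total` (percentages to 2 decimals)
#' @export
motivatorSummary <- function(fates, universe = NULL) {
    tab <- table(fates$category)
    n_unc <- tab[["unclassifiable"]]
    if (is.null(universe)) universe <- sum(tab) - n_unc
    grp <- function(a, b = NULL) {
        na <- sum(tab[a]); nb <- if (is.null(b)) 0L else sum(tab[b])
        c(na, nb)
    }
    rows <- list(
        Restoration = grp("restored", "inherited_LPR"),
        Emergence   = grp("emerged", "inherited_LPE"),
        Exclusion   = grp("excluded", "inherited_LPD"),
        Ordinary    = grp("inherited_increase", "inherited_decrease"),
        Unchanged   = grp("inherited_unchanged"),
        NoChange    = grp("absent_both", "inherited_fixed"))
    out <- data.frame(
        group = names(rows),
        n_allele = vapply(rows, `[`, 0, 1),
        n_allele_star = vapply(rows, `[`, 0, 2))
    out$n_total <- out$n_allele + out$n_allele_star
    out$pct_allele <- round(100 * out$n_allele / universe, 2)
    out$pct_allele_star <- round(100 * out$n_allele_star / universe, 2)
    out$pct_total <- round(100 * out$n_total / universe, 2)
    rownames(out) <- NULL
    attr(out, "universe") <- universe
    attr(out, "n_unclassifiable") <- n_unc
    out
}
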