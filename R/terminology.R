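#' @include AllClasses.R utils.R
NULL

#' Construct an ontology from an edge list
#'
#' @param child,parent parallel character vectors; each pair states
#'   \code{child} is-a \code{parent}.
#' @return An \linkS4class{OntologyGraph}.
#' @export
OntologyGraph <- function(child, parent) {
  new("OntologyGraph", child = as.character(child),
      parent = as.character(parent))
}

#' Read an ontology edge list from a two-column TSV (child, parent)
#'
#' @param path path to a TSV file with columns \code{child} and
#'   \code{parent} (a header line is expected).
#' @return An \linkS4class{OntologyGraph}.
#' @export
readOntology <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  OntologyGraph(d$child, d$parent)
}

.ontologyNodes <- function(ontology) {
  unique(c(ontology@child, ontology@parent))
}

#' Expand a seed concept set down the is-a hierarchy
#'
#' Starting from a seed set, repeatedly adds every concept that is-a
#' (directly) a concept already in the set; after \code{rounds} rounds the
#' result is the seed plus all concepts reachable by at most \code{rounds}
#' inverse is-a steps. The default of two rounds mirrors the common
#' curation practice of one subsumption expansion repeated once with the
#' enlarged set; \code{rounds = Inf} gives the transitive closure.
#'
#' @param seed character vector of seed concepts, or a
#'   \linkS4class{TermSet} whose concepts are used as the seed.
#' @param ontology an \linkS4class{OntologyGraph}.
#' @param rounds number of expansion rounds (default 2; may be \code{Inf}).
#' @return A \linkS4class{TermSet} whose provenance records the round of
#'   first inclusion (\code{seed}, \code{expansion_round_1}, ...).
#' @examples
#' ont <- OntologyGraph(child = c("B", "C"), parent = c("A", "B"))
#' concepts(expandSeedTerms("A", ont, rounds = 2))
#' @export
expandSeedTerms <- function(seed, ontology, rounds = 2L) {
  if (is(seed, "TermSet")) seed <- concepts(seed)
  seed <- unique(as.character(seed))
  nodes <- .ontologyNodes(ontology)
  unknown <- setdiff(seed, nodes)
  if (length(unknown))
    stop("seed concept(s) not present in ontology: ",
         paste(unknown, collapse = ", "))
  current <- seed
  prov <- stats::setNames(rep("seed", length(seed)), seed)
  k <- 0L
  while (k < rounds) {
    k <- k + 1L
    children <- ontology@child[ontology@parent %in% current]
    newly <- setdiff(unique(children), current)
    if (!length(newly)) break
    prov[newly] <- sprintf("expansion_round_%d", k)
    current <- c(current, newly)
  }
  new("TermSet", concepts = current, provenance = unname(prov[current]),
      removed = character())
}

#' Remove blocklisted concepts from a term set
#'
#' Represents the manual curation step that drops terms generating many
#' false positives; the blocklist is explicit configuration, not code.
#' Removed concepts are retained with provenance
#' \code{removed_by_filter}.
#'
#' @param terms a \linkS4class{TermSet}.
#' @param blocklist character vector of concept ids to remove.
#' @return The filtered \linkS4class{TermSet}.
#' @export
filterTerms <- function(terms, blocklist) {
  stopifnot(is(terms, "TermSet"))
  blocklist <- as.character(blocklist)
  hit <- terms@concepts %in% blocklist
  new("TermSet",
      concepts = terms@concepts[!hit],
      provenance = terms@provenance[!hit],
      removed = unique(c(terms@removed, terms@concepts[hit])))
}

#' Construct a drug indication table
#'
#' @param drug_id character vector of drug identifiers.
#' @param ingredients list of character vectors (active ingredients).
#' @param indications list of character vectors (primary indications).
#' @return A \linkS4class{DrugIndicationTable}.
#' @export
DrugIndicationTable <- function(drug_id, ingredients, indications) {
  d <- data.frame(drug_id = as.character(drug_id), stringsAsFactors = FALSE)
  d$ingredients <- ingredients
  d$indications <- indications
  new("DrugIndicationTable", drugs = d)
}

#' Read a drug indication table from CSV
#'
#' Expects columns \code{drug_id}, \code{ingredients}, \code{indications},
#' the latter two semicolon-joined.
#'
#' @param path path to the CSV file.
#' @return A \linkS4class{DrugIndicationTable}.
#' @export
readDrugTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  DrugIndicationTable(d$drug_id,
                      strsplit(d$ingredients, ";", fixed = TRUE),
                      strsplit(d$indications, ";", fixed = TRUE))
}

#' Derive indication-specific drug ingredients
#'
#' Ingredients of drugs whose primary indications include the target
#' indication, minus every ingredient that also occurs in any drug having
#' a primary indication other than the target. The subtraction removes
#' ingredients shared with drugs used for other conditions, so a mention
#' of a surviving ingredient is specific to treatment of the target
#' indication.
#'
#' @param table a \linkS4class{DrugIndicationTable}.
#' @param indication concept id of the target indication (e.g.
#'   \code{"depression"}).
#' @return Character vector of ingredient ids (possibly empty).
#' @export
deriveAntidepressantIngredients <- function(table, indication = "depression") {
  stopifnot(is(table, "DrugIndicationTable"))
  d <- table@drugs
  hasInd <- vapply(d$indications, function(x) indication %in% x, logical(1))
  if (!any(hasInd))
    stop("indication not present in table: ", indication)
  target <- unique(unlist(d$ingredients[hasInd]))
  otherInd <- vapply(d$indications,
                     function(x) length(setdiff(x, indication)) > 0,
                     logical(1))
  tainted <- unique(unlist(d$ingredients[otherInd]))
  sort(setdiff(target, tainted))
}

#' Keep only assertive annotations
#'
#' Drops term/drug-mention annotations flagged as negated or attributed
#' to family history; such mentions do not assert the condition in the
#' patient and are excluded from phenotype criteria and model features.
#' Row order is preserved.
#'
#' @param events an event data.frame with \code{negated} and
#'   \code{family_history} columns.
#' @return The subsequence of rows with both flags FALSE.
#' @export
usableAnnotations <- function(events) {
  keep <- !events$negated & !events$family_history
  events[keep, , drop = FALSE]
}

#' Write / read a term set with provenance
#'
#' One concept per line with its provenance tag; removed concepts carry
#' \code{removed_by_filter}.
#'
#' @param terms a \linkS4class{TermSet}.
#' @param path file path.
#' @return \code{readTermSet} returns a \linkS4class{TermSet};
#'   \code{writeTermSet} returns \code{path} invisibly.
#' @export
writeTermSet <- function(terms, path) {
  prov <- conceptProvenance(terms)
  utils::write.csv(data.frame(concept = names(prov), provenance = unname(prov),
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTermSet
#' @export
readTermSet <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  rem <- d$provenance == "removed_by_filter"
  new("TermSet", concepts = d$concept[!rem], provenance = d$provenance[!rem],
      removed = d$concept[rem])
}
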