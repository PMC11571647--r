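#' Intersect candidate gene sets from the three transcriptomic analyses
#'
#' Combines per-trait elastic-net selections, per-trait hub-gene sets and
#' per-trait DEG sets into the study's candidate structure:
#' `en_all_traits` holds the genes with non-zero effects for every trait
#' (the multi-trait candidate rule), and per trait the three-way overlap is
#' `en_all_traits` intersected with that trait's hubs and DEGs. Venn region
#' counts over (EN-all-traits, hubs, DEGs) are emitted per trait.
#'
#' @param en_selected Named list (per trait) of character vectors of
#'   EN-selected genes.
#' @param hub_sets Named list (per trait) of hub gene vectors.
#' @param deg_sets Named list (per trait) of DEG vectors.
#' @return List of class `"candidate_sets"`: `en_selected`, `hub_genes`,
#'   `degs`, `en_all_traits`, `overlap_per_trait`, `venn_per_trait`.
#' @export
intersect_gene_candidates <- function(en_selected, hub_sets, deg_sets) {
  if (!length(en_selected)) stop("empty elastic-net selection list")
  traits <- names(en_selected)
  en_selected <- lapply(en_selected, unique)
  hub_sets <- lapply(hub_sets, unique)
  deg_sets <- lapply(deg_sets, unique)
  en_all <- Reduce(intersect, en_selected)
  overlap <- venn <- setNames(vector("list", length(traits)), traits)
  for (tr in traits) {
    h <- hub_sets[[tr]] %||% character(0)
    d <- deg_sets[[tr]] %||% character(0)
    overlap[[tr]] <- sort(Reduce(intersect, list(en_all, h, d)))
    venn[[tr]] <- .venn3(en_all, h, d, c("EN", "hub", "DEG"))
  }
  structure(list(en_selected = en_selected, hub_genes = hub_sets,
                 degs = deg_sets, en_all_traits = sort(en_all),
                 overlap_per_trait = overlap, venn_per_trait = venn),
            class = "candidate_sets")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Region counts of a 3-set Venn diagram; the 7 disjoint regions always sum
# to the union size.
.venn3 <- function(A, B, C, labels = c("A", "B", "C")) {
  inA <- function(x) x %in% A
  inB <- function(x) x %in% B
  inC <- function(x) x %in% C
  u <- unique(c(A, B, C))
  reg <- c(sum(inA(u) & !inB(u) & !inC(u)),
           sum(!inA(u) & inB(u) & !inC(u)),
           sum(!inA(u) & !inB(u) & inC(u)),
           sum(inA(u) & inB(u) & !inC(u)),
           sum(inA(u) & !inB(u) & inC(u)),
           sum(!inA(u) & inB(u) & inC(u)),
           sum(inA(u) & inB(u) & inC(u)))
  names(reg) <- c(labels[1], labels[2], labels[3],
                  paste(labels[1], labels[2], sep = "&"),
                  paste(labels[1], labels[3], sep = "&"),
                  paste(labels[2], labels[3], sep = "&"),
                  paste(labels, collapse = "&"))
  c(reg, union = length(u))
}

#' Intersect SNP candidates from eGWAS and per-SNP trait association
#'
#' Overlap of the eGWAS hits (at the suggestive threshold, by convention)
#' with the SNPs significant for at least one trait in the per-SNP GLM.
#' Duplicated ids are deduplicated.
#'
#' @param egwas_hits Character vector of eGWAS-significant SNP ids.
#' @param glm_hits Character vector (or list of per-trait vectors) of
#'   GLM-significant SNP ids.
#' @return List: `egwas_significant`, `glm_significant`, `overlap`.
#' @export
intersect_snp_candidates <- function(egwas_hits, glm_hits) {
  if (is.list(glm_hits)) glm_hits <- unique(unlist(glm_hits))
  e <- unique(egwas_hits)
  g <- unique(glm_hits)
  list(egwas_significant = sort(e), glm_significant = sort(g),
       overlap = sort(intersect(e, g)))
}
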