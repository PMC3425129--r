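#' Curated Rab family presence/absence compendium
#'
#' A lineage-resolution presence/absence matrix for the 20 candidate
#' ancestral (LECA) Rab subfamilies across ten representative eukaryotic
#' lineages, mapped onto the four eukaryotic supergroups (Unikonta,
#' Excavata, Archaeplastida, SAR+CCTH).  The matrix encodes reported
#' occurrence patterns at lineage (not species) resolution; cells that
#' rest on sparse single-lineage evidence are marked in the accompanying
#' provenance table (`rab_provenance()`), which assigns each presence call
#' a confidence grade.
#'
#' Salient encoded patterns: Rab29 occurs only in unikonts and in the
#' heterolobosean excavates, making it the single family found in fewer
#' than three supergroups; the green-algal (Chlorophyta) repertoire
#' carries 14 of the 20 families and defines the archaeplastid presence
#' set; basal fungi carry 13.
#'
#' @return A [presence_matrix()] of 20 families x 10 taxa.
#' @seealso [rab_rootings()], [rab_ledgers()], [leca_dollo()]
#' @export
#' @examples
#' m <- rab_presence()
#' families_in_at_least(m, 3)$count
rab_presence <- function() {
  families <- c("Rab1", "Rab2", "Rab4", "Rab5", "Rab6", "Rab7", "Rab8",
                "Rab11", "Rab14", "Rab18", "Rab21", "Rab22", "Rab23",
                "Rab24", "Rab28", "Rab29", "Rab32", "RabL4", "RabX1",
                "Rab7L1")
  taxa <- c("Metazoa", "Choanoflagellata", "Fungi", "Amoebozoa",
            "Heterolobosea", "Kinetoplastida", "Chlorophyta",
            "Streptophyta", "Heterokonta", "Apicomplexa")
  supergroups <- c(Metazoa = "Unikonta", Choanoflagellata = "Unikonta",
                   Fungi = "Unikonta", Amoebozoa = "Unikonta",
                   Heterolobosea = "Excavata", Kinetoplastida = "Excavata",
                   Chlorophyta = "Archaeplastida",
                   Streptophyta = "Archaeplastida",
                   Heterokonta = "SAR+CCTH", Apicomplexa = "SAR+CCTH")

  # presence sets per taxon (family names)
  sets <- list(
    # metazoans retain the full ancestral complement
    Metazoa = families,
    Choanoflagellata = setdiff(families, c("Rab24", "RabX1")),
    # basal-fungal repertoire (13 families)
    Fungi = c("Rab1", "Rab2", "Rab4", "Rab5", "Rab6", "Rab7", "Rab8",
              "Rab11", "Rab18", "Rab23", "Rab32", "RabL4", "RabX1"),
    Amoebozoa = c("Rab1", "Rab2", "Rab4", "Rab5", "Rab6", "Rab7", "Rab8",
                  "Rab11", "Rab14", "Rab18", "Rab21", "Rab22", "Rab23",
                  "Rab28", "Rab32", "Rab7L1"),
    # the Rab-rich heterolobosean excavates carry every candidate family,
    # including the sole excavate Rab29 occurrence
    Heterolobosea = families,
    Kinetoplastida = c("Rab1", "Rab2", "Rab4", "Rab5", "Rab6", "Rab7",
                       "Rab11", "Rab14", "Rab18", "Rab21", "Rab23",
                       "Rab28", "Rab32"),
    # the 14-family green-algal repertoire
    Chlorophyta = c("Rab1", "Rab2", "Rab4", "Rab5", "Rab6", "Rab7", "Rab8",
                    "Rab11", "Rab18", "Rab21", "Rab23", "Rab24", "Rab28",
                    "RabL4"),
    # land-plant lineage: green-algal set minus Rab24, Rab28, RabL4
    Streptophyta = c("Rab1", "Rab2", "Rab4", "Rab5", "Rab6", "Rab7", "Rab8",
                     "Rab11", "Rab18", "Rab21", "Rab23"),
    Heterokonta = c("Rab1", "Rab2", "Rab4", "Rab5", "Rab6", "Rab7", "Rab8",
                    "Rab11", "Rab14", "Rab18", "Rab21", "Rab22", "Rab23",
                    "Rab28", "Rab32", "RabL4", "RabX1", "Rab7L1"),
    # apicomplexan parasites retain 11 families
    Apicomplexa = c("Rab1", "Rab2", "Rab4", "Rab5", "Rab6", "Rab7", "Rab8",
                    "Rab11", "Rab14", "Rab18", "Rab21")
  )
  m <- sapply(taxa, function(tx) families %in% sets[[tx]])
  rownames(m) <- families
  presence_matrix(m, supergroups)
}

#' The three eukaryotic rooting hypotheses
#'
#' * `unikont_bikont`: root between unikonts and all bikont supergroups.
#' * `excavate_adjacent`: root between the excavates and all other
#'   supergroups.
#' * `archaeplastida_outgroup`: Archaeplastida sister to everything else,
#'   with the uncertain excavate position handled by exclusion; the
#'   variant `archaeplastida_outgroup_excavata_inside` instead places the
#'   excavates with the Archaeplastida.
#'
#' @return Named list of [rooting_hypothesis()] objects.
#' @export
rab_rootings <- function() {
  list(
    unikont_bikont = rooting_hypothesis(
      "unikont_bikont", "Unikonta",
      c("Excavata", "Archaeplastida", "SAR+CCTH")),
    excavate_adjacent = rooting_hypothesis(
      "excavate_adjacent", "Excavata",
      c("Unikonta", "Archaeplastida", "SAR+CCTH")),
    archaeplastida_outgroup = rooting_hypothesis(
      "archaeplastida_outgroup", "Archaeplastida",
      c("Unikonta", "SAR+CCTH"), excluded = "Excavata"),
    archaeplastida_outgroup_excavata_inside = rooting_hypothesis(
      "archaeplastida_outgroup_excavata_inside",
      c("Archaeplastida", "Excavata"), c("Unikonta", "SAR+CCTH"))
  )
}

#' Curated gain/loss ledgers for four eukaryotic lineage paths
#'
#' Ordered event ledgers from the last eukaryotic common ancestor to a
#' model tip for the fungal, human (metazoan), plant and apicomplexan
#' lineages.  Loss events reflect the reported stepwise erosion of the
#' ancestral repertoire (for example the fungal path: seven families lost
#' by basal fungi, three more in non-basal fungi, Rab18 in the
#' Saccharomycotina, and Rab2/Rab4/RabX1 after the divergence of
#' *Yarrowia*, leaving *S. cerevisiae* with six).  The human path also
#' carries the metazoan-stem gains; their exact composition is not fully
#' resolvable at this resolution, so each gain is flagged `uncertain`.
#'
#' @return Named list of [event_ledger()] objects
#'   (`fungal`, `human`, `plant`, `apicomplexan`).
#' @export
#' @examples
#' led <- rab_ledgers()
#' losses_on_path(rownames(rab_presence()$present), led$fungal,
#'                "Saccharomyces_cerevisiae")
rab_ledgers <- function() {
  ev <- function(node, kind, fams, uncertain = FALSE) {
    data.frame(node = node, kind = kind, family = fams,
               uncertain = uncertain, stringsAsFactors = FALSE)
  }
  fungal <- event_ledger(
    c("LECA", "Opisthokonta", "Fungi_basal", "Dikarya", "Saccharomycotina",
      "post_Yarrowia", "Saccharomyces_cerevisiae"),
    rbind(
      ev("Fungi_basal", "loss", c("Rab14", "Rab21", "Rab22", "Rab24",
                                  "Rab28", "Rab29", "Rab7L1")),
      ev("Dikarya", "loss", c("Rab23", "Rab32", "RabL4")),
      ev("Saccharomycotina", "loss", "Rab18"),
      ev("post_Yarrowia", "loss", c("Rab2", "Rab4", "RabX1"))
    ))
  human <- event_ledger(
    c("LECA", "Opisthokonta", "Metazoa", "Vertebrata", "Homo_sapiens"),
    rbind(
      ev("Metazoa", "gain",
         c("Rab3", "Rab9", "Rab10", "Rab15", "Rab19", "Rab20", "Rab26",
           "Rab27", "Rab30", "Rab33", "Rab34", "Rab35", "Rab39", "Rab44",
           "Rab45", "RabX4", "RabX6"), uncertain = TRUE),
      ev("Vertebrata", "loss", c("RabX1", "Rab29")),
      ev("Vertebrata", "loss", c("RabX4", "RabX6"))
    ))
  plant <- event_ledger(
    c("LECA", "Archaeplastida", "Chlorophyta", "Streptophyta",
      "Angiospermae"),
    rbind(
      ev("Archaeplastida", "loss", c("Rab14", "Rab22", "Rab29", "Rab32",
                                     "Rab7L1", "RabX1")),
      ev("Streptophyta", "loss", c("Rab24", "Rab28", "RabL4")),
      ev("Angiospermae", "loss", "Rab23")
    ))
  apicomplexan <- event_ledger(
    c("LECA", "SAR", "Alveolata", "Apicomplexa", "Plasmodium_falciparum"),
    rbind(
      ev("Apicomplexa", "loss", c("Rab22", "Rab23", "Rab24", "Rab28",
                                  "Rab29", "Rab32", "RabL4", "RabX1",
                                  "Rab7L1"))
    ))
  list(fungal = fungal, human = human, plant = plant,
       apicomplexan = apicomplexan)
}

#' Provenance grades for the presence compendium
#'
#' One row per non-zero cell of [rab_presence()], with a confidence grade:
#' `reported` for patterns stated directly at this lineage resolution,
#' `inferred` for cells implied by retained-repertoire counts, and
#' `low-confidence` for cells resting on sparse or single-species
#' evidence.
#'
#' @return Data frame `family`, `taxon`, `value`, `confidence`, `note`.
#' @export
rab_provenance <- function() {
  m <- rab_presence()
  idx <- which(m$present, arr.ind = TRUE)
  fam <- rownames(m$present)[idx[, 1]]
  tax <- colnames(m$present)[idx[, 2]]
  conf <- rep("inferred", length(fam))
  note <- rep("member of the lineage's retained repertoire", length(fam))
  reported <- (tax == "Fungi") |
    (tax == "Chlorophyta") |
    (tax == "Apicomplexa") |
    (tax == "Metazoa") |
    (fam == "Rab29" & tax == "Heterolobosea") |
    (fam == "Rab7L1" & tax %in% c("Amoebozoa", "Metazoa", "Choanoflagellata")) |
    (fam == "RabX1" & tax %in% c("Heterokonta", "Fungi")) |
    (fam == "Rab28" & tax %in% c("Kinetoplastida", "Heterokonta")) |
    (fam == "Rab32" & tax == "Heterokonta")
  conf[reported] <- "reported"
  low <- (tax == "Heterolobosea" & fam != "Rab29") |
    (fam == "Rab24" & tax == "Chlorophyta") |
    (fam == "Rab28" & tax == "Chlorophyta") |
    (fam == "Rab21" & tax == "Streptophyta") |
    (tax == "Kinetoplastida" & fam %in% c("Rab23", "Rab32")) |
    (fam == "Rab7L1" & tax == "Heterokonta")
  conf[low] <- "low-confidence"
  note[fam == "Rab24" & tax == "Chlorophyta"] <-
    "single-species occurrence (one green alga)"
  note[fam == "Rab28" & tax == "Chlorophyta"] <-
    "single-species occurrence (one green alga)"
  note[fam == "Rab21" & tax == "Streptophyta"] <-
    "single-species occurrence (one angiosperm)"
  note[fam == "Rab29" & tax == "Heterolobosea"] <-
    "sole occurrence of Rab29 outside unikonts"
  note[tax == "Heterolobosea" & fam != "Rab29"] <-
    "attributed to the Rab-rich heterolobosean repertoire"
  data.frame(family = fam, taxon = tax, value = 1L, confidence = conf,
             note = note, stringsAsFactors = FALSE, row.names = NULL)
}
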