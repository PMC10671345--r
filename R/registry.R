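## The archetype registry: one descriptor per antithrombotic family, with
## function category, the published accession (provenance metadata), the
## expected mature-protein cysteine count, tandem-repeat structure and
## signal-peptide expectation. The packaged archetype sequences are
## SYNTHETIC stand-ins (deterministic constructs carrying each family's
## documented scaffold/repeat/length properties), shipped as
## extdata/archetypes_synthetic.faa and flagged by `synthetic = TRUE`.

.registry_table <- function() {
  fam <- function(family, category, accession, cys, rep_cys, rep_units, signal)
    data.frame(family = family, category = category, accession = accession,
               expected_cys = cys, repeat_cys = rep_cys,
               repeat_units = rep_units, signal = signal,
               synthetic = TRUE, stringsAsFactors = FALSE)
  co <- "coagulation inhibitor"; pl <- "platelet aggregation inhibitor"
  fi <- "fibrinolysis enhancer"; tp <- "tissue penetration enhancer"
  rbind(
    fam("hirudin",       co, "ALA22933.1",    6L, NA, NA, "yes"),
    fam("granulin",      co, "literature",   60L, 12L, 5L, "yes"),
    fam("antistasin",    co, "AAA29192.1",   20L, 10L, 2L, "yes"),
    fam("lefaxin",       co, "P86681.1",     NA,  NA, NA, "no"),
    fam("therostasin",   co, "AAF73958.1",   16L, NA, NA, "yes"),
    fam("hirustasin",    co, "P80302.1",     10L, NA, NA, "yes"),
    fam("guamerin",      co, "P46443.1",     10L, NA, NA, "yes"),
    fam("piguamerin",    co, "P81499.1",     10L, NA, NA, "yes"),
    fam("bdellastasin",  co, "P82107.1",     10L, NA, NA, "yes"),
    fam("poecistasin",   co, "literature",   10L, NA, NA, "yes"),
    fam("eglin",         co, "PDB:4H4F",     NA,  NA, NA, "yes"),
    fam("bdellin",       co, "AAK58688.1",    6L, NA, NA, "yes"),
    fam("LDTI",          co, "P80424.1",     12L,  6L, 2L, "yes"),
    fam("HMEI",          co, "literature",   10L, NA, NA, "yes"),
    fam("saratin",       pl, "PDB:2K13",      6L, NA, NA, "yes"),
    fam("apyrase",       pl, "XP_009028854.1", 2L, NA, NA, "mixed"),
    fam("lumbrokinase",  pl, "AAN28692.1",   14L, NA, NA, "yes"),
    fam("destabilase",   fi, "AAA96143.1",   14L, NA, NA, "yes"),
    fam("GGT",           fi, "literature",    6L, NA, NA, "no"),
    fam("LCI",           fi, "literature",    8L, NA, NA, "yes"),
    fam("hyaluronidase", tp, "AHV78514.1",    2L, NA, NA, "mixed")
  )
}

#' The antithrombotic family registry
#'
#' Descriptors for the 21 archetype families: function category (coagulation
#' inhibitor, platelet aggregation inhibitor, fibrinolysis enhancer, tissue
#' penetration enhancer), published accession (metadata only), expected
#' mature cysteine count (NA for the cysteine-free families lefaxin and
#' eglin), internal tandem-repeat structure (unit cysteines x unit count),
#' signal-peptide expectation, and the packaged synthetic archetype
#' sequence.
#'
#' @return data.frame with one row per family and an `archetype` column of
#'   mature protein sequences.
#' @export
family_registry <- function() {
  if (is.null(.hirumine_cache$registry)) {
    tab <- .registry_table()
    fa <- read_fasta(system.file("extdata", "archetypes_synthetic.faa",
                                 package = "hirumine"))
    stopifnot(all(tab$family %in% names(fa)))
    tab$archetype <- unname(fa[tab$family])
    stopifnot(nrow(tab) == 21L, !anyDuplicated(tab$family))
    .hirumine_cache$registry <- tab
  }
  .hirumine_cache$registry
}

#' Archetype sequences as a named vector
#'
#' @param registry a registry data.frame from [family_registry()].
#' @return named character vector family -> archetype protein.
#' @export
archetype_proteins <- function(registry = family_registry()) {
  setNames(registry$archetype, registry$family)
}

## families forming the hirustasin (antistasin-fold) superfamily
HIRUSTASIN_SUPERFAMILY <- c("hirustasin", "guamerin", "piguamerin",
                            "bdellastasin", "poecistasin")

#' Look up one family descriptor
#'
#' @param family family name.
#' @param registry registry table.
#' @return one-row data.frame.
#' @export
family_descriptor <- function(family, registry = family_registry()) {
  i <- match(family, registry$family)
  if (is.na(i)) stop("unknown family: ", family, call. = FALSE)
  registry[i, , drop = FALSE]
}
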