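# One-off builder for inst/extdata/archetypes_synthetic.faa (run from the
# repository root). Kept for provenance: the packaged archetypes are fully
# reproducible from this script.
# Deterministic synthetic archetype (mature) proteins carrying each family's
# documented cysteine scaffold / repeat structure. Run from repo root.

set.seed(20231103)
AA_NOC <- c("A","R","N","D","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")

rand_res <- function(n) sample(AA_NOC, n, replace = TRUE)

spread_cys <- function(len, k) {
  # roughly even placement with jitter, away from the termini
  base <- round(seq(3, len - 2, length.out = k))
  jit <- base + sample(-1:1, k, replace = TRUE)
  jit <- pmin(pmax(jit, 2), len - 1)
  while (anyDuplicated(jit)) jit[duplicated(jit)] <- jit[duplicated(jit)] + 1L
  sort(jit)
}

make_mature <- function(len, ncys) {
  r <- rand_res(len)
  if (ncys > 0) r[spread_cys(len, ncys)] <- "C"
  paste(r, collapse = "")
}

make_repeat <- function(unit_len, unit_cys, n_units, linker = 0, term = 0) {
  unit <- make_mature(unit_len, unit_cys)
  lk <- if (linker > 0) paste(rand_res(linker), collapse = "") else ""
  body <- paste(rep(unit, n_units), collapse = lk)
  if (term > 0) paste0(body, paste(rand_res(term), collapse = "")) else body
}

mutate_frac <- function(p, frac) {
  ch <- strsplit(p, "")[[1]]
  idx <- which(ch != "C")
  pick <- sample(idx, round(frac * length(idx)))
  ch[pick] <- vapply(ch[pick], function(a) sample(setdiff(AA_NOC, a), 1), "")
  paste(ch, collapse = "")
}

arch <- list()
arch$hirudin      <- make_mature(65, 6)
arch$granulin     <- make_repeat(60, 12, 5)             # 5 x 12-cys units
arch$antistasin   <- make_repeat(50, 10, 2, term = 8)   # 2 x 10-cys units
arch$lefaxin      <- make_mature(100, 0)
arch$therostasin  <- make_mature(80, 16)
hirustasin_base   <- make_mature(55, 10)
arch$hirustasin   <- hirustasin_base
arch$guamerin     <- mutate_frac(hirustasin_base, 0.30)
arch$piguamerin   <- mutate_frac(hirustasin_base, 0.30)
arch$bdellastasin <- mutate_frac(hirustasin_base, 0.30)
arch$poecistasin  <- mutate_frac(hirustasin_base, 0.30)
arch$eglin        <- make_mature(70, 0)
arch$bdellin      <- make_mature(110, 6)
arch$LDTI         <- make_repeat(30, 6, 2, linker = 5, term = 4)
arch$HMEI         <- make_mature(85, 10)
arch$saratin      <- make_mature(103, 6)
arch$apyrase      <- make_mature(330, 2)
arch$lumbrokinase <- make_mature(239, 14)
arch$destabilase  <- make_mature(115, 14)
arch$GGT          <- make_mature(380, 6)
arch$LCI          <- make_mature(67, 8)
arch$hyaluronidase <- make_mature(300, 2)

con <- file("inst/extdata/archetypes_synthetic.faa", "w")
writeLines(c(
  "; SYNTHETIC archetype stand-ins for the 21 leech antithrombotic families.",
  "; Not the accessioned reference proteins: deterministic constructs that",
  "; carry each family's documented length class, cysteine scaffold and",
  "; internal tandem-repeat structure, for simulation and testing."), con)
for (nm in names(arch)) {
  writeLines(paste0(">", nm, " synthetic_archetype"), con)
  s <- arch[[nm]]
  starts <- seq(1, nchar(s), by = 70)
  writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
}
close(con)
cat("wrote", length(arch), "archetypes\n")
cat("cys counts:\n")
print(vapply(arch, function(s) lengths(regmatches(s, gregexpr("C", s))), 1L))
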