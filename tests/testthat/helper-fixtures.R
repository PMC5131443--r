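# In-code fixtures shared across test files.

writeLinesTmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

biogridFixture <- function() writeLinesTmp(c(
  paste("Interactor A", "Interactor B", "Organism Interactor A",
        "Organism Interactor B", "Experimental System Type", sep = "\t"),
  "P1\tP2\t9606\t9606\tphysical",
  "P1\tP3\t9606\t10090\tphysical",
  "P2\tP3\t9606\t9606\tgenetic"))

dipFixture <- function() {
  row <- function(a, b, ty, ta = "taxid:9606(Homo sapiens)",
                  tb = "taxid:9606(Homo sapiens)")
    paste(c(a, b, rep("-", 7), ta, tb, ty), collapse = "\t")
  writeLinesTmp(c(
    row("D1", "D2", "physical interaction"),
    row("D1", "D3", "direct interaction"),
    row("D2", "D3", "genetic interaction"),
    row("D2", "D4", "physical interaction",
        ta = "taxid:10090(Mus musculus)")))
}

hprdFixture <- function() writeLinesTmp(c(
  "H1\tH2", "H1\tH1", "H2\tH3"))

intactFixture <- function() writeLinesTmp(c(
  paste("ID A", "ID B", "Type A", "Type B", "Interaction type", sep = "\t"),
  "I1\tI2\tprotein\tprotein\tdirect interaction",
  "I1\tI3\tgene\tprotein\tdirect interaction",
  "I2\tI3\tprotein\tprotein\tassociation"))

# a tiny metrics table with prescribed degree/betweenness
metricsFixture <- function(degree, betweenness = rev(seq_along(degree)),
                           ids = sprintf("M%02d", seq_along(degree))) {
  data.frame(protein = ids, degree = degree, betweenness = betweenness,
             stringsAsFactors = FALSE)
}

# small scenario used by several end-to-end tests (kept light)
smallScenarioConfig <- function(seed = 1, ...) {
  scenarioConfig(nProteins = 300, attachmentEdges = 3, nModules = 4,
                 cdsCodonsRange = c(60, 120), seed = seed, ...)
}
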