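# Shared fixtures built in code.

# tiny annotated experiment with all three host domains
makeToyVe <- function() {
  cnt <- rbind(
    Retroviridae = c(40L, 12L, 0L),
    Mimiviridae = c(12L, 30L, 5L),
    Siphoviridae = c(14L, 3L, 2L),
    UNCERTAIN_FAMILY = c(34L, 5L, 3L))
  colnames(cnt) <- c("s1", "s2", "s3")
  ViromeExperiment(cnt,
                   hostDomain = c(Retroviridae = "eukaryote",
                                  Mimiviridae = "eukaryote",
                                  Siphoviridae = "prokaryote_archaea",
                                  UNCERTAIN_FAMILY = "uncertain"),
                   sampleData = data.frame(
                     species = c("Aedes albopictus", "Mytilus edulis", "Nereis virens"),
                     phylum = c("Arthropoda", "Mollusca", "Annelida"),
                     habitat = c("terrestrial", "marine", "marine"),
                     row.names = c("s1", "s2", "s3")))
}
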