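# Small deterministic fixtures built in code.

tinyDag <- function() {
  DiseaseDAG(data.frame(parent = c("r", "r", "a", "a", "b"),
                        child = c("a", "b", "s1", "b2", "s2")))
}

# a 6-drug / 4-disease network with hand-set fingerprints and targets,
# cheap enough for model-level tests
tinyNet <- function(seed = 11L) {
  dag <- DiseaseDAG(data.frame(
    parent = c("root", "root", "c1", "c1", "c2", "c2"),
    child = c("c1", "c2", "c1a", "c1b", "c2a", "c2b")))
  seqs <- withr::with_seed(seed, c(
    t1 = randomPeptide(30), t2 = randomPeptide(30), t3 = randomPeptide(30)))
  fp <- rbind(c(1, 1, 1, 0, 0, 0), c(1, 1, 0, 0, 0, 0), c(1, 1, 1, 1, 0, 0),
              c(0, 0, 0, 1, 1, 1), c(0, 0, 1, 1, 1, 0), c(0, 0, 0, 0, 1, 1))
  drugs <- DrugRegistry(paste0("d", 1:6), fp,
                        setNames(list(c("t1"), c("t1", "t2"), c("t2"),
                                      c("t3"), c("t3"), c("t2", "t3")),
                                 paste0("d", 1:6)))
  diseases <- DiseaseRegistry(paste0("s", 1:4),
                              c("c1a", "c1b", "c2a", "c2b"), dag,
                              setNames(list("t1", c("t1", "t2"), "t3",
                                            "t3"), paste0("s", 1:4)))
  vals <- matrix(0, 6, 4, dimnames = list(paste0("d", 1:6),
                                          paste0("s", 1:4)))
  vals[1:3, 1:2] <- 1
  vals[4:6, 3:4] <- 1
  assoc <- new("AssociationMatrix", drugIds = paste0("d", 1:6),
               diseaseIds = paste0("s", 1:4), values = vals)
  buildHetNet(drugs, diseases, dag, seqs, assoc)
}

tinyModelConfig <- function(...) {
  gcmmConfig(embedDim = 8L, outChannels = 4L, ...)
}
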