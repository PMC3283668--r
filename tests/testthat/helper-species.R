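# shared scaffolding for the suite

three_defaults <- function() {
  sps <- lapply(c("T_bitextura", "T_epactia", "Triodia_sp"), default_species)
  names(sps) <- vapply(sps, `[[`, character(1), "name")
  sps
}

# hand 2-stage matrix used in several derived examples
hand_matrix <- function() matrix(c(0, 0.5, 2, 0.9), 2, 2)

# single-species landscape with every patch empty
empty_landscape <- function(sp = default_species("Triodia_sp"), edge = 4L) {
  l <- init_landscape(sp, edge = edge, total_capacity = 3906 * edge^2)
  l$pop[[sp$name]][] <- 0
  l
}
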