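# Small fixture builders shared across tests.

# Linear chain: boundary uptake of A (capped), conversion A -> B, demand
# for B. The conversion saturates its uptake cap when categorized UP.
make_chain_network <- function(cap = 10) {
  mets <- data.frame(id = c("A_e", "A_c", "B_c"),
                     compartment = c("e", "c", "c"),
                     stringsAsFactors = FALSE)
  metabolic_network(mets, list(
    reaction("EX_A", c(A_e = -1), lb = -cap, ub = 0),
    reaction("At", c(A_e = -1, A_c = 1), lb = 0, ub = 1000),
    reaction("R_AB", c(A_c = -1, B_c = 1), lb = 0, ub = 1000,
             gene_rule = "gAB"),
    reaction("DM_B", c(B_c = -1), lb = 0, ub = 1000)),
    id = "chain")
}

toy_conditions <- function(seed_trt = 1, seed_ctrl = 2) {
  net <- make_toy_network()
  bt <- apply_media_config(net, toy_media("octanoate"))
  bc <- apply_media_config(net, toy_media("control"))
  de_t <- simulate_de_table(synthetic_config(seed = seed_trt,
                                             preset = "octanoate"))
  de_c <- simulate_de_table(synthetic_config(seed = seed_ctrl,
                                             preset = "control"))
  list(net = net, bounded_trt = bt, bounded_ctrl = bc,
       cats_trt = map_genes_to_reactions(bt, categorize_genes(de_t)),
       cats_ctrl = map_genes_to_reactions(bc, categorize_genes(de_c)))
}
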