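## Declarative definition of the p53-pathway model: DNA-damage sensing by
## ATM, p53 arrester/killer phosphoforms, Mdm2 and Wip1 negative feedback
## loops, the PTEN-PIP3-AKT positive feedback, a bistable caspase switch,
## the p21 arrest arm, discrete promoter states for the four p53 target
## genes, and one-compartment inhibitor pharmacokinetics coupled through
## Mdm2 binding.
##
## The network topology follows the published p53 pathway architecture; rate
## constants quoted in the source literature (s_1, s_2, d_r1, d_r2, the
## IC_50-normalized binding equilibrium and the phenotype multipliers) are
## pinned, and the remaining constants are a calibrated reconstruction (see
## the methods vignette). Amount unit: copies/cell (drug pools: IC_50
## units); time unit: seconds.

#' Default parameter set of the p53 pathway model
#'
#' Named rate constants, all per-second (bimolecular: per copy per second).
#' `s_1`/`s_2` are the Wip1/PTEN transcription rate coefficients of a fully
#' active gene (0.1 and 0.03 mRNA/s nominal); `d_r1`/`d_r2` are the oral
#' inhibitor liberation and elimination rate coefficients (1/h and 0.25/h);
#' `ka_inh`/`kd_inh` give the inhibitor-Mdm2 association/dissociation with
#' dissociation constant 1 IC_50, so the equilibrium bound fraction is
#' `F = INH_B/(1 + INH_B)`.
#'
#' @return named numeric vector of parameters.
#' @export
default_parameters <- function() {
  c(
    ## irradiation / DNA damage
    k_dsb   = 35,        # double-strand breaks per Gy
    v_rep   = 5.5e-4,    # max repair rate, lesions/s
    K_rep   = 5,         # repair saturation, lesions

    ## ATM damage sensing. Activation and Wip1-mediated deactivation are
    ## Michaelis-Menten and operate near saturation (zero-order regime), so
    ## active ATM switches sharply when the Wip1 level crosses the balance
    ## point; together with the delayed Wip1 induction this yields
    ## relaxation oscillations under persistent damage.
    k_atm   = 16,        # max damage-gated activation flux, copies/s
    K_dam   = 14,        # damage level of half-maximal ATM activation
    Km_atm  = 120,       # Michaelis constant of the ATM phospho-cycle
    kd_atm  = 1e-4,      # spontaneous deactivation, 1/s
    kw_atm  = 6.7e-4,    # deactivation by Wip1, per Wip1 copy /s

    ## p53 synthesis, degradation, phosphoforms. The phospho/dephospho
    ## cycles are Michaelis-Menten (shared Km_p53) like the ATM cycle.
    s_p53   = 10,        # synthesis, copies/s
    d_p53   = 1e-5,      # basal degradation, 1/s (all forms)
    g_mdm   = 1e-7,      # Mdm2n-mediated degradation, per Mdm2n copy /s
    g_mdm_k = 3.5e-7,    # same for p53_killer (the inhibitor-sensitive channel)
    Km_p53  = 3800,      # Michaelis constant of the p53 phospho-cycles
    k_ph1   = 1.2e-3,    # Ser15 phosphorylation, per active-ATM copy /s
    k_deph1 = 1e-4,      # basal arrester dephosphorylation, 1/s
    k_wip_a = 6.5e-4,    # Wip1-mediated arrester dephosphorylation, per copy /s
    k_ph2   = 4e-3,      # arrester -> killer, per active-ATM copy /s
    k_deph2 = 5e-5,      # basal killer -> arrester, 1/s
    k_wip_k = 1.4e-4,    # Wip1-mediated killer -> arrester, per copy /s

    ## promoter switching (shared off-rate)
    q_off   = 6.3e-4,
    q0_mdm2 = 1e-4,  q1_mdm2 = 1e-7,
    q0_wip1 = 2e-6,  q1_wip1 = 2.6e-10,   # quadratic in p53A (tetramer)
    q0_pten = 5e-5,  q1_pten = 5.6e-11,   # quadratic in p53K (tetramer)
    q0_p21  = 5e-5,  q1_p21  = 3e-7,

    ## Mdm2 expression, transport, inhibitor binding
    s_mdm2  = 0.02,      # transcription per active allele, mRNA/s
    d_mdm2m = 1e-4,
    t_mdm2  = 0.03,      # translation per mRNA, 1/s
    d_mdm2c = 4e-4,
    k_imp   = 6e-8,      # nuclear import, AKTp-dependent
    d_mdm2n = 2.5e-4,
    ka_inh  = 1e-3,      # association with blood inhibitor, per IC_50 /s
    kd_inh  = 1e-3,      # dissociation, 1/s (K_d = 1 IC_50)

    ## Wip1 expression (s_1 = full-gene rate; factor 1/2 per allele)
    s_1     = 0.1,
    d_wip1m = 8e-5,
    t_wip1  = 0.023,
    d_wip1  = 2e-4,

    ## PTEN expression (long-lived protein: the apoptotic timer)
    s_2     = 0.03,
    d_ptenm = 1e-4,
    t_pten  = 5e-3,
    d_pten  = 1.8e-5,

    ## PIP2/PIP3 and AKT (zero-order AKT cycle: sharp switch in PIP3)
    k_pi3k  = 3e-4,
    k_pten  = 1.2e-7,
    k_pip_b = 1e-5,
    k_akt   = 4.2e-4,    # phosphorylation per PIP3 copy /s (saturating)
    k_dakt  = 2.5,       # max dephosphorylation flux, copies/s
    Km_akt  = 500,       # Michaelis constant of the AKT cycle

    ## p21 arrest arm
    s_p21   = 0.02,
    d_p21m  = 2e-4,
    t_p21   = 0.02,
    d_p21   = 3e-4,

    ## caspase module (bistable switch; commitment = Casp > casp_thresh)
    s_casp  = 0.5,
    d_casp0 = 5e-5,
    k_c1    = 2e-4,
    K_kill  = 4.06e4,
    k_c2    = 1e-3,
    K_cfb   = 4e3,
    d_casp  = 1e-4,
    casp_thresh = 5e3,

    ## pharmacokinetics (per second; 1/h and 0.25/h)
    d_r1    = 1 / 3600,
    d_r2    = 0.25 / 3600,
    q_drip  = 0          # zero-order drip inflow, IC_50 units/s
  )
}

species_row <- function(name, role, init, scalable) {
  data.frame(name = name, role = role, init = init, scalable = scalable,
             stringsAsFactors = FALSE)
}

rx_row <- function(id, k, reactants = "", products = "", rate = "",
                   hill = "", fac = 1, pk = FALSE) {
  data.frame(id = id, k = k, fac = fac, rate = rate, hill = hill,
             reactants = reactants, products = products, pk = pk,
             stringsAsFactors = FALSE)
}

#' Declarative definition of the p53 pathway network
#'
#' Returns the species and reaction tables that [build_network()] compiles.
#' Initial amounts are the unirradiated resting state of the nominal
#' (normal-cell) deterministic model. The same table drives both engines;
#' promoter-state species are discrete in the stochastic engine and become
#' occupancy fractions in the ODE approximation.
#'
#' @return list with data.frames `species` and `reactions`.
#' @export
network_definition <- function() {
  species <- rbind(
    species_row("DNAdam",  "damage-lesion",   0,     FALSE),
    species_row("ATMi",    "protein",         10000, TRUE),
    species_row("ATMa",    "protein",         0,     TRUE),
    species_row("p53",     "protein",         25212, TRUE),
    species_row("p53A",    "protein",         0,     TRUE),
    species_row("p53K",    "protein",         0,     TRUE),
    species_row("Mdm2m",   "mRNA",            55,    FALSE),
    species_row("Mdm2c",   "protein",         1693,  TRUE),
    species_row("Mdm2n",   "protein",         3866,  TRUE),
    species_row("Mdm2nI",  "protein-complex", 0,     TRUE),
    species_row("Wip1m",   "mRNA",            4,     FALSE),
    species_row("Wip1",    "protein",         455,   TRUE),
    species_row("PTENm",   "mRNA",            22,    FALSE),
    species_row("PTEN",    "protein",         6127,  TRUE),
    species_row("PIP2",    "protein",         28520, TRUE),
    species_row("PIP3",    "protein",         11480, TRUE),
    species_row("AKT",     "protein",         485,   TRUE),
    species_row("AKTp",    "protein",         9515,  TRUE),
    species_row("p21m",    "mRNA",            15,    FALSE),
    species_row("p21",     "protein",         980,   TRUE),
    species_row("ProC",    "protein",         1e4,   TRUE),
    species_row("Casp",    "protein",         0,     TRUE),
    species_row("Gm_off",  "DNA-state",       1.726, FALSE),
    species_row("Gm_on",   "DNA-state",       0.274, FALSE),
    species_row("Gw_off",  "DNA-state",       1.994, FALSE),
    species_row("Gw_on",   "DNA-state",       0.006, FALSE),
    species_row("Gp_off",  "DNA-state",       1.853, FALSE),
    species_row("Gp_on",   "DNA-state",       0.147, FALSE),
    species_row("G21_off", "DNA-state",       1.853, FALSE),
    species_row("G21_on",  "DNA-state",       0.147, FALSE),
    species_row("INHd",    "drug-pool",       0,     FALSE),
    species_row("INHb",    "drug-pool",       0,     FALSE)
  )

  reactions <- rbind(
    ## DNA damage repair (saturating: persistent damage at high lesion load)
    rx_row("repair",     "v_rep",  reactants = "DNAdam:1", hill = "DNAdam:K_rep:1"),
    ## ATM activation/deactivation
    rx_row("atm_act",    "k_atm",  reactants = "ATMi:1", products = "ATMa:1",
           hill = "DNAdam:K_dam:2;ATMi:Km_atm:1"),
    rx_row("atm_deact",  "kd_atm", reactants = "ATMa:1", products = "ATMi:1",
           rate = "ATMa:1"),
    rx_row("atm_wip1",   "kw_atm", reactants = "ATMa:1", products = "ATMi:1",
           rate = "Wip1:1", hill = "ATMa:Km_atm:1"),
    ## p53 synthesis / degradation
    rx_row("p53_syn",    "s_p53",  products = "p53:1"),
    rx_row("p53_deg",    "d_p53",  reactants = "p53:1",  rate = "p53:1"),
    rx_row("p53a_deg",   "d_p53",  reactants = "p53A:1", rate = "p53A:1"),
    rx_row("p53k_deg",   "d_p53",  reactants = "p53K:1", rate = "p53K:1"),
    rx_row("p53_mdm2",   "g_mdm",  reactants = "p53:1",  rate = "p53:1,Mdm2n:1"),
    rx_row("p53a_mdm2",  "g_mdm",  reactants = "p53A:1", rate = "p53A:1,Mdm2n:1"),
    rx_row("p53k_mdm2",  "g_mdm_k", reactants = "p53K:1", rate = "p53K:1,Mdm2n:1"),
    ## phosphoform conversions
    rx_row("p53_phos",   "k_ph1",  reactants = "p53:1",  products = "p53A:1",
           rate = "ATMa:1", hill = "p53:Km_p53:1"),
    rx_row("p53a_deph",  "k_deph1", reactants = "p53A:1", products = "p53:1",
           rate = "p53A:1"),
    rx_row("p53a_wip1",  "k_wip_a", reactants = "p53A:1", products = "p53:1",
           rate = "Wip1:1", hill = "p53A:Km_p53:1"),
    rx_row("p53a_phos2", "k_ph2",  reactants = "p53A:1", products = "p53K:1",
           rate = "ATMa:1", hill = "p53A:Km_p53:1"),
    rx_row("p53k_deph",  "k_deph2", reactants = "p53K:1", products = "p53A:1",
           rate = "p53K:1"),
    rx_row("p53k_wip1",  "k_wip_k", reactants = "p53K:1", products = "p53A:1",
           rate = "Wip1:1", hill = "p53K:Km_p53:1"),
    ## Mdm2 gene / mRNA / protein / transport / inhibitor binding
    rx_row("gm_on0",     "q0_mdm2", reactants = "Gm_off:1", products = "Gm_on:1",
           rate = "Gm_off:1"),
    rx_row("gm_on1",     "q1_mdm2", reactants = "Gm_off:1", products = "Gm_on:1",
           rate = "Gm_off:1,p53A:1"),
    rx_row("gm_off",     "q_off",  reactants = "Gm_on:1", products = "Gm_off:1",
           rate = "Gm_on:1"),
    rx_row("mdm2_tx",    "s_mdm2", products = "Mdm2m:1", rate = "Gm_on:1"),
    rx_row("mdm2m_deg",  "d_mdm2m", reactants = "Mdm2m:1", rate = "Mdm2m:1"),
    rx_row("mdm2_tl",    "t_mdm2", products = "Mdm2c:1", rate = "Mdm2m:1"),
    rx_row("mdm2c_deg",  "d_mdm2c", reactants = "Mdm2c:1", rate = "Mdm2c:1"),
    rx_row("mdm2_imp",   "k_imp",  reactants = "Mdm2c:1", products = "Mdm2n:1",
           rate = "Mdm2c:1,AKTp:1"),
    rx_row("mdm2n_deg",  "d_mdm2n", reactants = "Mdm2n:1", rate = "Mdm2n:1"),
    rx_row("inh_bind",   "ka_inh", reactants = "Mdm2n:1", products = "Mdm2nI:1",
           rate = "Mdm2n:1,INHb:1"),
    rx_row("inh_unbind", "kd_inh", reactants = "Mdm2nI:1", products = "Mdm2n:1",
           rate = "Mdm2nI:1"),
    rx_row("mdm2nI_deg", "d_mdm2n", reactants = "Mdm2nI:1", rate = "Mdm2nI:1"),
    ## Wip1 (negative feedback on ATM and p53 phosphoforms)
    rx_row("gw_on0",     "q0_wip1", reactants = "Gw_off:1", products = "Gw_on:1",
           rate = "Gw_off:1"),
    rx_row("gw_on1",     "q1_wip1", reactants = "Gw_off:1", products = "Gw_on:1",
           rate = "Gw_off:1,p53A:2"),
    rx_row("gw_off",     "q_off",  reactants = "Gw_on:1", products = "Gw_off:1",
           rate = "Gw_on:1"),
    rx_row("wip1_tx",    "s_1",    products = "Wip1m:1", rate = "Gw_on:1",
           fac = 0.5),
    rx_row("wip1m_deg",  "d_wip1m", reactants = "Wip1m:1", rate = "Wip1m:1"),
    rx_row("wip1_tl",    "t_wip1", products = "Wip1:1", rate = "Wip1m:1"),
    rx_row("wip1_deg",   "d_wip1", reactants = "Wip1:1", rate = "Wip1:1"),
    ## PTEN (killer-driven; positive feedback via AKT)
    rx_row("gp_on0",     "q0_pten", reactants = "Gp_off:1", products = "Gp_on:1",
           rate = "Gp_off:1"),
    rx_row("gp_on1",     "q1_pten", reactants = "Gp_off:1", products = "Gp_on:1",
           rate = "Gp_off:1,p53K:2"),
    rx_row("gp_off",     "q_off",  reactants = "Gp_on:1", products = "Gp_off:1",
           rate = "Gp_on:1"),
    rx_row("pten_tx",    "s_2",    products = "PTENm:1", rate = "Gp_on:1",
           fac = 0.5),
    rx_row("ptenm_deg",  "d_ptenm", reactants = "PTENm:1", rate = "PTENm:1"),
    rx_row("pten_tl",    "t_pten", products = "PTEN:1", rate = "PTENm:1"),
    rx_row("pten_deg",   "d_pten", reactants = "PTEN:1", rate = "PTEN:1"),
    ## PIP2/PIP3 cycle and AKT
    rx_row("pip_phos",   "k_pi3k", reactants = "PIP2:1", products = "PIP3:1",
           rate = "PIP2:1"),
    rx_row("pip_deph",   "k_pten", reactants = "PIP3:1", products = "PIP2:1",
           rate = "PIP3:1,PTEN:1"),
    rx_row("pip_deph0",  "k_pip_b", reactants = "PIP3:1", products = "PIP2:1",
           rate = "PIP3:1"),
    rx_row("akt_phos",   "k_akt",  reactants = "AKT:1", products = "AKTp:1",
           rate = "PIP3:1", hill = "AKT:Km_akt:1"),
    rx_row("akt_deph",   "k_dakt", reactants = "AKTp:1", products = "AKT:1",
           hill = "AKTp:Km_akt:1"),
    ## p21 arrest arm
    rx_row("g21_on0",    "q0_p21", reactants = "G21_off:1", products = "G21_on:1",
           rate = "G21_off:1"),
    rx_row("g21_on1",    "q1_p21", reactants = "G21_off:1", products = "G21_on:1",
           rate = "G21_off:1,p53A:1"),
    rx_row("g21_off",    "q_off",  reactants = "G21_on:1", products = "G21_off:1",
           rate = "G21_on:1"),
    rx_row("p21_tx",     "s_p21",  products = "p21m:1", rate = "G21_on:1"),
    rx_row("p21m_deg",   "d_p21m", reactants = "p21m:1", rate = "p21m:1"),
    rx_row("p21_tl",     "t_p21",  products = "p21:1", rate = "p21m:1"),
    rx_row("p21_deg",    "d_p21",  reactants = "p21:1", rate = "p21:1"),
    ## caspase switch
    rx_row("proc_syn",   "s_casp", products = "ProC:1"),
    rx_row("proc_deg",   "d_casp0", reactants = "ProC:1", rate = "ProC:1"),
    rx_row("casp_act",   "k_c1",   reactants = "ProC:1", products = "Casp:1",
           rate = "ProC:1", hill = "p53K:K_kill:4"),
    rx_row("casp_fb",    "k_c2",   reactants = "ProC:1", products = "Casp:1",
           rate = "ProC:1", hill = "Casp:K_cfb:2"),
    rx_row("casp_deg",   "d_casp", reactants = "Casp:1", rate = "Casp:1"),
    ## pharmacokinetics (advanced analytically in the stochastic engine)
    rx_row("pk_lib",     "d_r1",   reactants = "INHd:1", products = "INHb:1",
           rate = "INHd:1", pk = TRUE),
    rx_row("pk_elim",    "d_r2",   reactants = "INHb:1", rate = "INHb:1",
           pk = TRUE),
    rx_row("pk_drip",    "q_drip", products = "INHb:1", pk = TRUE)
  )

  list(species = species, reactions = reactions)
}
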