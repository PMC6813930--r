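# Regenerates src/air_rhs.c with parameter #defines taken from the canonical
# ordering in R/air-params.R, so C indices can never drift from the registry.
source("R/air-params.R")

nm <- .air_param_names
extra <- c("SNETT", "SNETB", "PCAP")  # appended runtime parameters
all_nm <- c(nm, extra)
defines <- paste0("#define P_", gsub("[^A-Za-z0-9_]", "_", all_nm),
                  " parms[", seq_along(all_nm) - 1L, "]")

header <- c(
  "/* Compiled right-hand side of the acute inflammatory response (AIR)",
  " * model for deSolve. Parameter order is generated from the registry in",
  " * R/air-params.R (do not edit the #define block by hand); the final",
  " * three slots are the runtime net growth rates and the blood-pathogen",
  " * overflow cap. State vector: 18 AIR states plus the TLR switch R as",
  " * component 19 (zero derivative; flipped by events at root crossings).",
  " */",
  "#include <R.h>",
  "#include <math.h>",
  "",
  sprintf("static double parms[%d];", length(all_nm)),
  "",
  defines,
  "",
  "void air_initmod(void (*odeparms)(int *, double *)) {",
  sprintf("  int N = %d;", length(all_nm)),
  "  odeparms(&N, parms);",
  "}",
  "",
  "static double hu1(double x, double n, double h) {",
  "  if (x < 0.0) x = 0.0;",
  "  return pow(x, h) / (1.0 + pow(x / n, h));",
  "}",
  "static double hu2(double x, double n, double h) {",
  "  double xh;",
  "  if (x < 0.0) x = 0.0;",
  "  xh = pow(x, h);",
  "  return xh / (xh + pow(n, h));",
  "}",
  "static double hd(double x, double n, double h) {",
  "  if (x < 0.0) x = 0.0;",
  "  return 1.0 / (1.0 + pow(x / n, h));",
  "}",
  ""
)

body <- c(
  "void air_derivs(int *neq, double *t, double *y, double *ydot,",
  "                double *yout, int *ip) {",
  "  double PT, MT, NT, B, PB, MR, MA, NR, NAc, iNOSd, iNOS, eNOS, NO3,",
  "         TNF, IL6, IL10, IL12, TI, R, NO, transloc, gate, dmg, actM, actN,",
  "         tiex;",
  "  if (ip[0] < 1) error(\"nout must be >= 1\");",
  "  PT = y[0] > 0.0 ? y[0] : 0.0;",
  "  MT = y[1] > 0.0 ? y[1] : 0.0;",
  "  NT = y[2] > 0.0 ? y[2] : 0.0;",
  "  B  = y[3] > 0.0 ? y[3] : 0.0;",
  "  PB = y[4] > 0.0 ? y[4] : 0.0;",
  "  MR = y[5] > 0.0 ? y[5] : 0.0;",
  "  MA = y[6] > 0.0 ? y[6] : 0.0;",
  "  NR = y[7] > 0.0 ? y[7] : 0.0;",
  "  NAc = y[8] > 0.0 ? y[8] : 0.0;",
  "  iNOSd = y[9] > 0.0 ? y[9] : 0.0;",
  "  iNOS = y[10] > 0.0 ? y[10] : 0.0;",
  "  eNOS = y[11] > 0.0 ? y[11] : 0.0;",
  "  NO3 = y[12] > 0.0 ? y[12] : 0.0;",
  "  TNF = y[13] > 0.0 ? y[13] : 0.0;",
  "  IL6 = y[14] > 0.0 ? y[14] : 0.0;",
  "  IL10 = y[15] > 0.0 ? y[15] : 0.0;",
  "  IL12 = y[16] > 0.0 ? y[16] : 0.0;",
  "  TI = y[17];",
  "  R = y[18] > 0.5 ? 1.0 : 0.0;",
  "",
  "  NO = iNOS * (1.0 + P_k_NOMA * (MA + NAc)) + eNOS;",
  "  /* translocation is gated by barrier loss: an intact barrier (B = 1)",
  "   * admits no pathogen into the blood */",
  "  gate = 1.0 - B + P_b_B; if (gate > 1.0) gate = 1.0;",
  "  transloc = P_theta_P * PT * gate / (1.0 + P_k_PTB * B);",
  "  dmg = 1.0 - TI; if (dmg < 0.0) dmg = 0.0;",
  "",
  "  /* net growth minus density-dependent mortality: a drug-suppressed",
  "   * (negative) net rate still kills above the carrying capacity */",
  "  ydot[0] = P_SNETT * PT - P_S_P * PT * PT / P_kappa_PT - transloc",
  "            - P_k_PTMT * MT * PT - P_k_PTNT * NT * PT;",
  "  ydot[1] = P_S_MT * NT * P_M_v / (1.0 + P_k_MTB * B) - P_k_MT * MT;",
  "  ydot[2] = P_S_NT * R * P_N_v /",
  "            ((1.0 + P_k_NTB * B) * (1.0 + P_k_NTMT * MT)) - P_k_NT * NT;",
  "  /* second degradation term is pathogen-driven (coefficient is on the",
  "   * pathogen count scale) */",
  "  /* barrier erosion needs TLR activation and a high pathogen burden */",
  "  /* healing suppressed by burden relative to carrying capacity */",
  "  ydot[3] = P_S_B * (1.0 - B) / (1.0 + P_k_BPT * PT / P_kappa_PT)",
  "            - (P_k_BR + P_k_BNT * PT) * R * B",
  "              * hu2(PT, P_x_BP, P_h_BP);",
  "  ydot[4] = P_SNETB * PB + transloc - P_k_PS * PB / (P_x_PS + PB)",
  "            - P_k_PBNA * NAc * hu2(PB, P_x_PN, 2.0);",
  "",
  "  actM = (P_k_MP * hu2(PB, P_x_MP, 2.0) + P_k_MD * hu2(dmg, P_x_MD, 4.0))",
  "         * (hu2(TNF, P_x_MTNF, 2.0) + P_k_M6 * hu2(IL6, P_x_M6, 2.0))",
  "         * hd(IL10, P_x_M10, 2.0);",
  "  ydot[5] = -actM * MR - P_k_MR * (MR - P_S_M);",
  "  ydot[6] = actM * MR - P_k_MA * MA;",
  "",
  "  actN = (P_k_NP * hu2(PB, P_x_NP, 1.0) + P_k_ND * hu1(dmg, P_x_ND, 2.0)",
  "          + P_k_NTNF * hu1(TNF, P_x_NTNF, 1.0)",
  "          + P_k_N6 * hu1(IL6, P_x_N6, 2.0)) * hd(IL10, P_x_N10, 2.0);",
  "  ydot[7] = -actN * NR - P_k_NR * (NR - P_S_N);",
  "  ydot[8] = actN * NR - P_k_NA * NAc;",
  "",
  "  ydot[9] = (P_k_INOSN * NAc + P_k_INOSM * MA + P_k_INOSEC *",
  "             (hu1(TNF, P_x_INOSTNF, 2.0)",
  "              + P_k_INOS6 * hu1(IL6, P_x_INOS6, 2.0)))",
  "            * hd(IL10, P_x_INOS10, 2.0) * hd(NO, P_x_INOSNO, 4.0)",
  "            - P_k_INOSd * iNOSd;",
  "  ydot[10] = P_k_INOS * (iNOSd - iNOS);",
  "  ydot[11] = P_k_ENOSEC * hd(TNF, P_x_ENOSTNF, 1.0)",
  "             * hd(PB, P_x_ENOSP, 1.0) - P_k_ENOS * eNOS;",
  "  ydot[12] = P_k_NO3 * (NO - NO3);",
  "",
  "  ydot[13] = (P_k_TNFN * NAc + P_k_TNFM * MA) * hd(IL10, P_x_TNF10, 2.0)",
  "             * hd(IL6, P_x_TNF6, 3.0) - P_k_TNF * TNF;",
  "  ydot[14] = (P_k_6N * NAc + MA)",
  "             * (P_k_6M + P_k_6TNF * hu2(TNF, P_x_6TNF, 2.0)",
  "                + P_k_6NO * hu2(NO, P_x_6NO, 2.0))",
  "             * hd(IL10, P_x_610, 2.0) * hd(IL6, P_x_66, 1.0)",
  "             - P_k_6 * (IL6 - P_S_6);",
  "  ydot[15] = (P_k_10N * NAc + MA)",
  "             * (P_k_10MA + P_k_10TNF * hu2(TNF, P_x_10TNF, 4.0)",
  "                + P_k_106 * hu2(IL6, P_x_106, 4.0))",
  "             * ((1.0 - P_k_10R) * hd(IL12, P_x_1012, 4.0) + P_k_10R)",
  "             - P_k_10 * (IL10 - P_S_10);",
  "  ydot[16] = P_k_12M * MA * hd(IL10, P_x_1210, 2.0) - P_k_12 * IL12;",
  "",
  "  tiex = TI - P_TI_min; if (tiex < 0.0) tiex = 0.0;",
  "  ydot[17] = P_k_D * (1.0 - TI) * tiex",
  "             - tiex * P_k_D6 * hu2(IL6, P_x_D6, 6.0)",
  "               / (P_x_DNO * P_x_DNO + NO * NO);",
  "",
  "  ydot[18] = 0.0; /* TLR switch: piecewise constant */",
  "  yout[0] = NO;",
  "}",
  "",
  "/* Roots: upper TLR threshold, lower TLR threshold, blood-pathogen cap */",
  "void air_root(int *neq, double *t, double *y, int *ng, double *gout) {",
  "  gout[0] = y[0] - P_PT_plus;",
  "  gout[1] = y[0] - P_PT_minus;",
  "  gout[2] = y[4] - P_PCAP;",
  "}",
  "",
  "/* Event applied at a root: hysteresis rule for the TLR switch */",
  "void air_event(int *n, double *t, double *y) {",
  "  if (y[18] < 0.5 && y[0] > P_PT_plus) y[18] = 1.0;",
  "  else if (y[18] > 0.5 && y[0] < P_PT_minus) y[18] = 0.0;",
  "}"
)

writeLines(c(header, body), "src/air_rhs.c")
cat("wrote src/air_rhs.c with", length(all_nm), "parameters\n")
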