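/* Compiled right-hand sides for the two gene-network model classes,
 * driven through deSolve's compiled-function interface.
 *
 * The model is passed once per integration via grn_set_model() as a flat
 * double vector:
 *   [0] model class: 1 = mrna_protein, 2 = protein_only
 *   [1] G  number of genes
 *   [2] R  number of regulations
 *   [3] shared protein degradation rate (class 1) / unused (class 2)
 *   per-gene blocks of 4, gene g (0-based), at 4 + 4*g:
 *     class 1: [promoter, rbs, mrna_deg_factor, deleted]
 *     class 2: [deg, basal, 0, deleted]
 *   per-regulation blocks of 8, at 4 + 4*G + 8*r:
 *     [source(1-based), n_targets, target1(1-based), target2(or 0),
 *      sign(+1/-1), Kd, h, syn]
 *
 * State layout: class 1 -> y = [mRNA_1..mRNA_G, P_1..P_G];
 *               class 2 -> y = [P_1..P_G].
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <string.h>

static double *model_buf = NULL;
static R_xlen_t model_len = 0;

SEXP grn_set_model(SEXP v)
{
    R_xlen_t n = XLENGTH(v);
    if (model_buf) {
        R_Free(model_buf);
        model_buf = NULL;
    }
    model_buf = R_Calloc(n, double);
    memcpy(model_buf, REAL(v), n * sizeof(double));
    model_len = n;
    return R_NilValue;
}

static double hill_term(double P, double Kd, double h, double sign)
{
    double x;
    if (P < 0.0) P = 0.0;
    x = pow(P / Kd, h);
    if (!R_FINITE(x)) /* saturated: overflowing (P/Kd)^h */
        return (sign > 0.0) ? 1.0 : 0.0;
    if (sign > 0.0)
        return x / (1.0 + x);
    return 1.0 / (1.0 + x);
}

void grn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    if (!model_buf)
        error("grn_derivs called before grn_set_model");
    int cls = (int) model_buf[0];
    int G = (int) model_buf[1];
    int R = (int) model_buf[2];
    double pdeg = model_buf[3];
    const double *gene = model_buf + 4;
    const double *reg = model_buf + 4 + 4 * G;
    /* protein concentrations */
    const double *P = (cls == 1) ? (y + G) : y;

    for (int g = 0; g < G; g++) {
        if (cls == 1) {
            ydot[g] = 0.0;
            ydot[G + g] = 0.0;
        } else {
            ydot[g] = 0.0;
        }
    }

    for (int g = 0; g < G; g++) {
        const double *gb = gene + 4 * g;
        if (gb[3] > 0.5) /* deleted: mRNA and protein eliminated */
            continue;
        if (cls == 1) {
            double prod = gb[0]; /* promoter strength, empty product = 1 */
            for (int r = 0; r < R; r++) {
                const double *rb = reg + 8 * r;
                int nt = (int) rb[1];
                int hit = ((int) rb[2] == g + 1) ||
                          (nt == 2 && (int) rb[3] == g + 1);
                if (!hit)
                    continue;
                prod *= hill_term(P[(int) rb[0] - 1], rb[5], rb[6], rb[4]);
            }
            ydot[g] = prod - gb[2] * y[g];            /* mRNA */
            ydot[G + g] = gb[1] * y[g] - pdeg * P[g]; /* protein */
        } else {
            double prod = gb[1]; /* basal (0 for regulated genes) */
            for (int r = 0; r < R; r++) {
                const double *rb = reg + 8 * r;
                int nt = (int) rb[1];
                int hit = ((int) rb[2] == g + 1) ||
                          (nt == 2 && (int) rb[3] == g + 1);
                if (!hit)
                    continue;
                prod += rb[7] *
                        hill_term(P[(int) rb[0] - 1], rb[5], rb[6], rb[4]);
            }
            ydot[g] = prod - gb[0] * y[g];
        }
    }
}
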