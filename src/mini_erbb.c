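/* Reduced ErbB -> ERK/Akt -> c-Fos model, deSolve compiled-code convention.
 *
 * Parameter vector layout (shared with R side, see miniErbBModel()):
 *  0 ka1   1 ki1   2 ka3   3 ki3   4 kx    5 kdx   6 kfb   7 kmek
 *  8 kdmek 9 kerk 10 kderk 11 kd  12 kakt 13 kdakt 14 ksm 15 K
 * 16 n    17 kdm  18 ksf  19 kdf  20 kpf  21 kdpf  22 ksd 23 kdd
 * 24 R1tot 25 R3tot 26 Xtot 27 MEKtot 28 ERKtot 29 Akttot
 * 30 EGF  31 HRG   (ligand doses, appended per condition)
 *
 * State layout:
 *  0 R1a 1 R3a 2 Xa 3 pMEK 4 pERK 5 pAkt 6 Fm 7 Fos 8 pFos 9 Dusp
 */

#include <R.h>
#include <Rmath.h>

#define N_PARMS 32

static double p[N_PARMS];

void minierbb_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

void minierbb_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double R1a = y[0], R3a = y[1], Xa = y[2], pMEK = y[3], pERK = y[4],
           pAkt = y[5], Fm = y[6], Fos = y[7], pFos = y[8], Dusp = y[9];
    double S = R1a + R3a;
    /* guard: BDF steps may poke slightly negative pERK; pow() of a
       negative base with non-integer exponent would be NaN */
    double e = pERK > 0.0 ? pERK : 0.0;
    double en = R_pow(e, p[16]);
    double Kn = R_pow(p[15], p[16]);

    ydot[0] = p[0] * p[30] * (p[24] - R1a) - p[1] * R1a;
    ydot[1] = p[2] * p[31] * (p[25] - R3a) - p[3] * R3a;
    ydot[2] = p[4] * S * (p[26] - Xa) - p[5] * (1.0 + p[6] * pERK) * Xa;
    ydot[3] = p[7] * Xa * (p[27] - pMEK) - p[8] * pMEK;
    ydot[4] = p[9] * pMEK * (p[28] - pERK)
              - p[10] * (1.0 + p[11] * Dusp) * pERK;
    ydot[5] = p[12] * S * (p[29] - pAkt) - p[13] * pAkt;
    ydot[6] = p[14] * en / (Kn + en) - p[17] * Fm;
    ydot[7] = p[18] * Fm - p[19] * Fos - p[20] * pERK * Fos + p[21] * pFos;
    ydot[8] = p[20] * pERK * Fos - p[21] * pFos - p[19] * pFos;
    ydot[9] = p[22] * pERK - p[23] * Dusp;
}
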