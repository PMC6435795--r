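context,group,strategy,ef
CDK2-4KD1,all,AASS,7.0
CDK2-4KD1,all,RbN,7.0
CDK2-4KD1,all,Zscore,6.0
CDK2-4KD1,all,RbR,7.0
CDK2-4KD1,all,RbV,6.8
CDK2-4KD1,all,ECR,6.0
CDK2-1FVV,all,AASS,20.0
CDK2-1FVV,all,RbN,13.0
CDK2-1FVV,all,Zscore,19.0
CDK2-1FVV,all,RbR,17.0
CDK2-1FVV,all,RbV,19.1
CDK2-1FVV,all,ECR,21.0
ESR1-1XP9,all,AASS,11.4
ESR1-1XP9,all,RbN,18.9
ESR1-1XP9,all,Zscore,18.1
ESR1-1XP9,all,RbR,17.7
ESR1-1XP9,all,RbV,19.9
ESR1-1XP9,all,ECR,21.7
ESR1-3ERT,all,AASS,10.2
ESR1-3ERT,all,RbN,17.3
ESR1-3ERT,all,Zscore,20.5
ESR1-3ERT,all,RbR,18.5
ESR1-3ERT,all,RbV,21.1
ESR1-3ERT,all,ECR,22.8
ADRB2-3PDS,all,AASS,3.2
ADRB2-3PDS,all,RbN,8.0
ADRB2-3PDS,all,Zscore,9.2
ADRB2-3PDS,all,RbR,9.0
ADRB2-3PDS,all,RbV,9.2
ADRB2-3PDS,all,ECR,11.9
ADRB2-4LDO,all,AASS,5.1
ADRB2-4LDO,all,RbN,15.8
ADRB2-4LDO,all,Zscore,10.0
ADRB2-4LDO,all,RbR,10.0
ADRB2-4LDO,all,RbV,9.5
ADRB2-4LDO,all,ECR,10.4
CAH2-1BCD,all,AASS,8.8
CAH2-1BCD,all,RbN,5.6
CAH2-1BCD,all,Zscore,10.5
CAH2-1BCD,all,RbR,9.5
CAH2-1BCD,all,RbV,8.3
CAH2-1BCD,all,ECR,8.3
CAH2-4PQ7,all,AASS,6.8
CAH2-4PQ7,all,RbN,6.3
CAH2-4PQ7,all,Zscore,9.8
CAH2-4PQ7,all,RbR,8.1
CAH2-4PQ7,all,RbV,9.3
CAH2-4PQ7,all,ECR,9.0
CDK2-MS,score,AASS,18.0
CDK2-MS,score,RbN,13.0
CDK2-MS,score,Zscore,18.0
CDK2-MS,rank,RbR,13.0
CDK2-MS,rank,RbV,17.2
CDK2-MS,rank,ECR,16.0
ESR1-MS,score,AASS,17.3
ESR1-MS,score,RbN,22.1
ESR1-MS,score,Zscore,22.1
ESR1-MS,rank,RbR,19.3
ESR1-MS,rank,RbV,22.3
ESR1-MS,rank,ECR,23.2
ADRB2-MS,score,AASS,4.3
ADRB2-MS,score,RbN,12.9
ADRB2-MS,score,Zscore,9.7
ADRB2-MS,rank,RbR,8.5
ADRB2-MS,rank,RbV,10.2
ADRB2-MS,rank,ECR,12.9
CAH2-MS,score,AASS,9.0
CAH2-MS,score,RbN,7.8
CAH2-MS,score,Zscore,10.2
CAH2-MS,rank,RbR,9.5
CAH2-MS,rank,RbV,9.0
CAH2-MS,rank,ECR,10.0
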